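test_that("log transform maps TPM to log2(v + 1) and is guarded", {
  m <- matrix(c(0, 1, 7, 3), nrow = 2,
              dimnames = list(c("G1", "G2"), c("S1", "S2")))
  expr <- as_expr_matrix(m, units = "TPM")
  lg <- log_transform(expr)
  expect_equal(unclass(lg)[, "S1"], c(G1 = 0, G2 = 1))
  expect_equal(unclass(lg)["G1", "S2"], 3) # log2(8)
  expect_warning(lg2 <- log_transform(lg), "already log2TPM")
  expect_equal(lg2, lg)
  expect_error(as_expr_matrix(m - 1, units = "TPM"), "non-negative")
})

test_that("expression matrix construction enforces labels and shape", {
  m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(rownames(as_expr_matrix(m, "TPM")), c("G1", "G2"))
  expect_error(as_expr_matrix(matrix(1:4, 2), "TPM"), "row names")
  expect_error(as_expr_matrix(m[, 1, drop = FALSE], "TPM"), "2 samples")
  dup <- m
  rownames(dup) <- c("G1", "G1")
  expect_error(as_expr_matrix(dup, "TPM"), "duplicate gene")
})

test_that("per-gene z-scores standardize rows and flag degenerate genes", {
  m <- matrix(c(2^1 - 1, 2^2 - 1, 2^3 - 1, # log2(v+1) = 1, 2, 3
                2^5 - 1, 2^5 - 1, 2^5 - 1),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("G1", "CONST"), c("S1", "S2", "S3")))
  z <- zscore_genes(as_expr_matrix(m, "TPM"))
  expect_equal(unname(z["G1", ]), c(-1, 0, 1))
  expect_equal(unname(z["CONST", ]), c(0, 0, 0))
  expect_equal(attr(z, "degenerate"), "CONST")

  # non-degenerate rows have mean 0 and unit sample SD
  expect_equal(mean(z["G1", ]), 0)
  expect_equal(stats::sd(z["G1", ]), 1)

  # z-score units pass through unchanged
  zin <- as_expr_matrix(matrix(stats::rnorm(6), 2,
                               dimnames = list(c("A", "B"), c("s1", "s2", "s3"))),
                        units = "zscore")
  expect_equal(unclass(zscore_genes(zin)), unclass(zin),
               ignore_attr = TRUE)

  bad <- matrix(c(1, NA, 2, 3), 2,
                dimnames = list(c("G1", "G2"), c("S1", "S2")))
  expect_error(zscore_genes(as_expr_matrix(bad, "log2TPM")), "G2.*S1")
})

test_that("z-scores are shift invariant and permutation equivariant", {
  expr <- random_expr(15, 6, seed = 11, units = "log2TPM")
  z1 <- zscore_genes(expr)
  shifted <- unclass(expr)
  shifted["G003", ] <- shifted["G003", ] + 50
  z2 <- zscore_genes(as_expr_matrix(shifted, "log2TPM"))
  expect_equal(unclass(z1), unclass(z2), tolerance = 1e-12,
               ignore_attr = TRUE)

  perm <- c(4, 1, 6, 2, 5, 3)
  zp <- zscore_genes(as_expr_matrix(unclass(expr)[, perm], "log2TPM"))
  expect_equal(unclass(zp), unclass(z1)[, perm], ignore_attr = TRUE)
})

test_that("raw WE scores follow the weighted-mean formula", {
  panel <- as_ddr_panel(tibble::tibble(
    gene = c("G1", "G2", "G3"),
    pathway = c("HR", "HR", "TLS"),
    esf = c(2, 1, 1)
  ))
  z <- as_zmat(matrix(c(1, -1, 1.5, 0, 0, 0), nrow = 3, byrow = TRUE,
                      dimnames = list(c("G1", "G2", "G3"), c("S1", "S2"))))
  z["G1", ] <- c(1, 0)
  z["G2", ] <- c(-1, 0)
  z["G3", ] <- c(1.5, 0)
  we <- we_scores(z, panel)
  # (1*2 + (-1)*1) / 2 = 0.5
  expect_equal(we$raw["HR", "S1"], 0.5)
  # single-gene pathway passes through
  expect_equal(we$raw["TLS", "S1"], 1.5)
  # all-zero sample scores 0 everywhere by linearity
  expect_equal(unname(we$raw[, "S2"]), c(0, 0))
  expect_equal(unname(we$n_genes_used), c(2L, 1L))
})

test_that("pathways absent from the data are dropped; strict mode deflates", {
  panel <- as_ddr_panel(tibble::tibble(
    gene = c("G1", "G2", "MISSING"),
    pathway = c("HR", "HR", "TLS"),
    esf = c(1, 1, 1)
  ))
  z <- as_zmat(matrix(c(1, 2, 3, 4), nrow = 2,
                      dimnames = list(c("G1", "G2"), c("S1", "S2"))))
  expect_warning(we <- we_scores(z, panel), "TLS")
  expect_equal(rownames(we$raw), "HR")
  expect_equal(we$unmatched, "MISSING")

  # strict mode divides by the full panel pathway size
  panel2 <- as_ddr_panel(tibble::tibble(
    gene = c("G1", "G2"), pathway = c("HR", "HR"), esf = c(1, 1)))
  z2 <- as_zmat(matrix(c(1, 1), nrow = 1,
                       dimnames = list("G1", c("S1", "S2"))))
  expect_equal(we_scores(z2, panel2)$raw["HR", "S1"], 1)
  expect_equal(we_scores(z2, panel2, strict = TRUE)$raw["HR", "S1"], 0.5)

  z3 <- as_zmat(matrix(1:4, 2, dimnames = list(c("X1", "X2"), c("S1", "S2"))))
  expect_error(we_scores(z3, panel), "no panel genes")
})

test_that("WE scores are ESF-neutral, linear, and match the naive oracle", {
  for (seed in 1:5) {
    expr <- random_expr(20, 8, seed = seed)
    z <- zscore_genes(expr)
    panel <- random_panel(rownames(z)[1:16], n_pathways = 4, seed = seed + 100)

    # oracle equivalence (vectorized vs triple loop)
    we <- we_scores(z, panel)
    expect_lt(max(abs(we$raw - naive_we(z, panel))), 1e-10)

    # ESF neutrality: uniform weights reduce to per-pathway mean z
    flat <- as_ddr_panel(dplyr::mutate(tibble::as_tibble(unclass(panel)), esf = 1))
    we1 <- we_scores(z, flat)
    for (p in rownames(we1$raw)) {
      genes_p <- flat$gene[flat$pathway == p]
      expect_lt(max(abs(we1$raw[p, ] -
                          colMeans(z[genes_p, , drop = FALSE]))), 1e-12)
    }

    # linearity in z
    z2 <- as_zmat(unclass(z) * 0.3 + 0.1)
    zsum <- as_zmat(unclass(z) + unclass(z2))
    expect_equal(we_scores(zsum, panel)$raw,
                 we_scores(z, panel)$raw + we_scores(z2, panel)$raw,
                 tolerance = 1e-12)
  }
})

test_that("scaling standardizes pathway rows across samples", {
  raw <- matrix(c(0.5, -0.5, 1, 1), nrow = 2, byrow = TRUE,
                dimnames = list(c("HR", "BER"), c("S1", "S2")))
  we <- fake_scores(raw)
  we$scaled <- NULL
  expect_warning(sc <- scale_we(we), "BER")
  expect_equal(unname(sc$scaled["HR", ]), c(1, -1) / sqrt(2), tolerance = 1e-9)
  expect_equal(unname(sc$scaled["BER", ]), c(0, 0))

  expr <- random_expr(20, 8, seed = 3)
  sc2 <- we_score_pipeline(expr, random_panel(rownames(expr)[1:15], 3, seed = 4))
  expect_lt(max(abs(rowMeans(sc2$scaled))), 1e-9)
  expect_equal(unname(apply(sc2$scaled, 1, stats::sd)),
               rep(1, nrow(sc2$scaled)), tolerance = 1e-9)
})

test_that("signature scores are weighted means over matched genes", {
  z <- as_zmat(matrix(c(1, 2, -1, 0), nrow = 2, byrow = TRUE,
                      dimnames = list(c("A", "B"), c("S1", "S2"))))
  expect_equal(as.numeric(signature_score(z, c(A = 1, B = -1))),
               c((1 + 1) / 2, (2 + 0) / 2))
  expect_equal(as.numeric(signature_score(z, c(A = 1, B = 1))["S2"]), 1)
  s <- signature_score(z, c(A = 1, B = 1, ZZZ = 1))
  expect_equal(attr(s, "missing"), "ZZZ")
  expect_error(signature_score(z, c(Q = 1)), "no signature genes")
  expect_error(signature_score(z, c(A = 0, B = 0)), "not all zero")
})
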