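test_that("size factors reproduce the median-of-ratios hand computation", {
  counts <- matrix(c(100, 200, 10, 20, 40, 80), nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  sf <- size_factors(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)
  expect_equal(unname(round(sf, 4)), c(0.7071, 1.4142))

  # identical columns -> unit factors; scaling a column scales its factor
  same <- cbind(s1 = c(5, 50, 500), s2 = c(5, 50, 500))
  expect_equal(unname(size_factors(same)), c(1, 1))
  scaled <- same; scaled[, 2] <- scaled[, 2] * 3
  expect_equal(unname(size_factors(scaled)), c(1, 3) / sqrt(3))

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "no gene")
})

test_that("size factors agree with the standard DESeq2 estimator", {
  set.seed(42)
  counts <- matrix(rnbinom(600, mu = 200, size = 10), ncol = 6,
                   dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(size_factors(counts)), unname(ref), tolerance = 1e-12)
})

test_that("normalization divides by factors and is idempotent", {
  counts <- matrix(c(100, 200), 1, dimnames = list("g1", c("s1", "s2")))
  norm <- normalize_counts(counts, c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(norm), matrix(c(141.4214, 141.4214), 1),
               tolerance = 1e-6)
  m <- matrix(c(100, 200, 10, 20, 40, 80), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(normalize_counts(m, c(1, 1)), m)
  expect_equal(unname(size_factors(normalize_counts(m))), c(1, 1),
               tolerance = 1e-9)
  zero <- rbind(m, g4 = c(0, 0))
  expect_equal(unname(normalize_counts(zero)["g4", ]), c(0, 0))
  expect_error(normalize_counts(m, 1), "length")
})

test_that("the expression floor applies per condition to replicate means", {
  design <- c(A_1 = "A", A_2 = "A", B_1 = "B", B_2 = "B", C_1 = "C",
              C_2 = "C")
  norm <- rbind(g_in = c(12, 12, 11, 11, 15, 15),
                g_out = c(12, 12, 9, 9, 15, 15),
                g_zero = rep(0.5, 6))
  colnames(norm) <- names(design)
  expect_equal(expressed_genes(norm, design, floor = 10), "g_in")
  expect_setequal(expressed_genes(norm, design, floor = 0),
                  c("g_in", "g_out", "g_zero"))
})

test_that("DEG calls apply the fold-change and p-value gates jointly", {
  design <- c(CTRL_1 = "CTRL", CTRL_2 = "CTRL", CTRL_3 = "CTRL",
              HL_1 = "HL", HL_2 = "HL", HL_3 = "HL")
  norm <- rbind(up = c(10, 10.01, 9.99, 50, 50.02, 49.98),
                null = c(30, 31, 29, 30.5, 29.5, 30),
                gated = c(100, 101, 99, 186, 187, 185))
  colnames(norm) <- names(design)
  res <- call_degs(norm, design, "HL", "CTRL")
  up <- res[res$gene_id == "up", ]
  expect_equal(up$log2fc, log2(51 / 11), tolerance = 1e-9)
  expect_true(up$is_deg)
  expect_equal(up$direction, "up")
  nl <- res[res$gene_id == "null", ]
  expect_lt(abs(nl$log2fc), 0.1)
  expect_false(nl$is_deg)
  # |log2fc| below the gate stays non-DEG no matter how small p is
  gated <- res[res$gene_id == "gated", ]
  expect_lt(gated$p_value, 1e-4)
  expect_lt(abs(gated$log2fc), 1)
  expect_false(gated$is_deg)
  expect_equal(gated$direction, "none")

  expect_error(call_degs(norm[, c(1, 4)], design[c(1, 4)], "HL", "CTRL"),
               "replicates")
})

test_that("DEG calling recovers planted fold changes on synthetic counts", {
  cfg <- sim_config(seed = 21, n_genes = 1000, deg_fraction = 0.1,
                    deg_log2fc = 2, nb_dispersion = 0.05, n_replicates = 3)
  truth <- simulate_genome(cfg)$truth
  counts <- simulate_counts(truth, cfg)
  norm <- normalize_counts(counts$rna)
  design <- sub("_[0-9]+$", "", colnames(norm))
  names(design) <- colnames(norm)
  res <- call_degs(norm, design, "LT", "CTRL")
  planted <- truth$lfc_LT != 0
  sens <- mean(res$is_deg[planted])
  fpr <- mean(res$is_deg[!planted])
  expect_gte(sens, 0.9 - 0.05)
  expect_lte(fpr, 0.05 + 0.05)
  # planted direction is recovered for every true call
  hit <- planted & res$is_deg
  expect_true(all(sign(res$log2fc[hit]) == sign(truth$lfc_LT[hit])))
})

test_that("translation efficiency follows the ratio definition", {
  design <- c(CTRL_1 = "CTRL", CTRL_2 = "CTRL")
  rna <- rbind(g1 = c(100, 100), g2 = c(40, 40))
  rpf <- rbind(g1 = c(50, 50), g2 = c(40, 40))
  colnames(rna) <- colnames(rpf) <- names(design)
  te <- translation_efficiency(rna, rpf, design, pseudocount = 0,
                               floor = 0)
  expect_equal(te$te[te$gene_id == "g1"], 0.5)
  expect_equal(te$te[te$gene_id == "g2"], 1)
  expect_true(all(is.na(te$torso_te)))

  # doubling RNA halves TE at zero pseudocount
  te2 <- translation_efficiency(rna * 2, rpf, design, pseudocount = 0,
                                floor = 0)
  expect_equal(te2$te, te$te / 2)

  # pseudocount floors the zero/zero case at 1
  z <- rbind(gz = c(0, 0)); colnames(z) <- names(design)
  tez <- translation_efficiency(z, z, design, pseudocount = 1, floor = 0)
  expect_equal(tez$te, 1)
})

test_that("relative TE is invariant to a common scaling of all RPF libraries", {
  # median-of-ratios factors are unchanged by a global rescaling (every
  # count-to-geomean ratio is preserved), so absolute TE carries the
  # scale while TE comparisons between genes and conditions do not
  cfg <- sim_config(seed = 13, n_genes = 80)
  counts <- simulate_counts(simulate_genome(cfg)$truth, cfg)
  design <- sub("_[0-9]+$", "", colnames(counts$rna))
  names(design) <- colnames(counts$rna)
  rna_n <- normalize_counts(counts$rna)
  te1 <- translation_efficiency(rna_n, normalize_counts(counts$rpf),
                                design, pseudocount = 0)
  te2 <- translation_efficiency(rna_n, normalize_counts(counts$rpf * 5L),
                                design, pseudocount = 0)
  ratio <- te2$te / te1$te
  expect_lt(diff(range(ratio)), 1e-9)        # one common factor only
  # cross-condition TE contrasts are exactly preserved per gene
  contrast <- function(te) {
    lt <- te[te$condition == "LT", ]; ct <- te[te$condition == "CTRL", ]
    lt$te[match(ct$gene_id, lt$gene_id)] / ct$te
  }
  expect_equal(contrast(te1), contrast(te2), tolerance = 1e-12)
})

test_that("torso counts exclude both extremity windows", {
  # 300-bp CDS, uniform depth 2: torso = 300 - 60 - 33 = 207 positions
  g <- gene_models("g1", "chr", "+", 101, 400)
  depth <- numeric(600); depth[101:400] <- 2
  expect_equal(torso_counts(fix_track(depth), g), 2 * 207)

  # all depth confined to the extremity windows -> torso sum 0
  part <- extremity_partition()
  d2 <- numeric(600)
  d2[region_positions(g, part, "extremity")] <- 5
  expect_equal(torso_counts(fix_track(d2), g), 0)

  # minus-strand mirror of the torso arithmetic
  gm <- gene_models("g1", "chr", "-", 101, 400)
  dm <- numeric(600); dm[101:400] <- 2
  expect_equal(torso_counts(fix_track(dm, strand = "-"), gm), 2 * 207)

  # 90-bp CDS leaves no torso under the default windows
  g90 <- gene_models("tiny", "chr", "+", 101, 190)
  expect_error(torso_counts(fix_track(depth), g90), "torso is empty")
})

test_that("hypergeometric enrichment matches an exact combinatorial oracle", {
  # oracle: direct tail sum of the hypergeometric pmf via choose()
  oracle <- function(k, m, N, n)
    sum(vapply(k:min(m, n), function(i)
      choose(m, i) * choose(N - m, n - i), numeric(1))) / choose(N, n)

  bg <- paste0("g", 1:100)
  query <- paste0("g", 1:5)
  term_map <- list(hit = paste0("g", c(1:3, 50:56)),     # 3 of 10 in query
                   miss = paste0("g", 90:99))            # disjoint
  res <- hypergeom_enrichment(query, term_map, bg)
  p_hit <- res$p[res$term == "hit"]
  expect_equal(p_hit, oracle(3, 10, 100, 5), tolerance = 1e-10)
  expect_equal(p_hit, 0.00664, tolerance = 1e-3)
  expect_equal(res$p[res$term == "miss"], 1)

  # random configurations against the oracle
  set.seed(1)
  for (i in 1:20) {
    N <- sample(20:200, 1)
    bgN <- paste0("x", seq_len(N))
    n <- sample(3:15, 1)
    m <- sample(3:15, 1)
    q <- sample(bgN, n)
    term <- list(t = sample(bgN, m))
    k <- length(intersect(q, term$t))
    got <- hypergeom_enrichment(q, term, bgN)$p
    want <- if (k == 0) 1 else oracle(k, m, N, n)
    expect_equal(got, want, tolerance = 1e-10)
  }

  # BH identity at a single term; enriched flag respects alpha
  single <- hypergeom_enrichment(query, term_map["hit"], bg)
  expect_equal(single$p_adjusted, single$p)
  expect_true(single$enriched)
  expect_error(hypergeom_enrichment(query, term_map, character(0)),
               "empty background")
  expect_error(hypergeom_enrichment(c(query, "absent"), term_map, bg),
               "subset")
})
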