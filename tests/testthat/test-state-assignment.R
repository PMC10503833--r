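# Centroid label transfer, signature scores, decomposition, DEG, chi-square.

expr_fixture <- local({
  env <- new.env(parent = emptyenv())
  function() {
    if (is.null(env$x)) {
      cfg <- small_config()
      states <- names(cfg$state_proportions)
      truth <- data.frame(
        barcode = sprintf("x%04d", seq_len(30L * length(states))),
        state = rep(states, each = 30L), stringsAsFactors = FALSE)
      env$x <- c(simulate_expression(truth, cfg),
                 list(truth = truth, cfg = cfg))
    }
    env$x
  }
})

test_that("centroids are state means and survive library-size rescaling", {
  ex <- expr_fixture()
  labels <- truth_lookup(ex$truth, "state")
  mg <- unlist(ex$marker_map)
  ref <- build_centroids(ex$counts, labels, mg, target = 500)
  # single-state mean check against direct computation
  st <- colnames(ref$centroids)[1]
  ln <- lognorm(ex$counts, target = 500)
  expect_equal(ref$centroids[, st],
               Matrix::rowMeans(ln[mg, labels[colnames(ex$counts)] == st]))
  # doubling raw library sizes leaves centroids unchanged after normalization
  ref2 <- build_centroids(ex$counts * 2, labels, mg, target = 500)
  expect_equal(ref$centroids, ref2$centroids, tolerance = 1e-12)
  # planted markers have elevated centroid means in their home state
  for (st in names(ex$marker_map)) {
    own <- ref$centroids[ex$marker_map[[st]], st]
    other <- rowMeans(ref$centroids[ex$marker_map[[st]],
                                    colnames(ref$centroids) != st])
    expect_gt(mean(own - other), 0)
  }
  expect_error(build_centroids(ex$counts, labels, c(mg, "nope")),
               "absent")
  bad <- labels
  bad[1] <- "lonely-state"
  expect_error(build_centroids(ex$counts, bad, mg), "lonely-state")
})

test_that("a cell equal to a centroid classifies to it with r = 1", {
  ex <- expr_fixture()
  labels <- truth_lookup(ex$truth, "state")
  mg <- unlist(ex$marker_map)
  ref <- build_centroids(ex$counts, labels, mg)
  # craft a query whose lognorm marker vector equals a centroid: counts
  # 2^c - 1 with library already at target
  st <- colnames(ref$centroids)[3]
  v <- 2^ref$centroids[, st] - 1
  q <- Matrix::Matrix(matrix(v, ncol = 1), sparse = TRUE)
  dimnames(q) <- list(mg, "probe")
  ref_probe <- ref
  ref_probe$target <- sum(v)  # keep scaling neutral for the probe cell
  cls <- classify_cells(q, ref_probe)
  expect_equal(cls$label, st)
  expect_equal(cls$best_r, 1, tolerance = 1e-9)
})

test_that("noise cells fall below the 0.7 floor and zero-variance is flagged", {
  ex <- expr_fixture()
  labels <- truth_lookup(ex$truth, "state")
  mg <- unlist(ex$marker_map)
  ref <- build_centroids(ex$counts, labels, mg)
  set.seed(31)
  noise <- Matrix::Matrix(
    matrix(rpois(length(mg) * 20, 5), nrow = length(mg)), sparse = TRUE)
  dimnames(noise) <- list(mg, paste0("n", 1:20))
  cls <- classify_cells(noise, ref)
  expect_true(all(cls$label == "unassigned"))
  flat <- Matrix::Matrix(matrix(3, nrow = length(mg), ncol = 1),
                         sparse = TRUE, dimnames = list(mg, "flat"))
  expect_equal(classify_cells(flat, ref)$label, "unassigned")
})

test_that("self-classification recovers generator labels at high marker fold", {
  ex <- expr_fixture()
  labels <- truth_lookup(ex$truth, "state")
  mg <- unlist(ex$marker_map)
  ref <- build_centroids(ex$counts, labels, mg)
  cls <- classify_cells(ex$counts, ref)
  acc <- mean(cls$label == labels[cls$barcode])
  expect_gte(acc, 0.95)
})

test_that("signature scores are centered under the null and monotone", {
  # null: every gene iid, so any signature matches its background exactly
  set.seed(17)
  m <- Matrix::Matrix(matrix(rpois(1000 * 300, 5), nrow = 1000),
                      sparse = TRUE)
  dimnames(m) <- list(sprintf("g%04d", 1:1000), sprintf("c%03d", 1:300))
  null_genes <- sample(rownames(m), 25)
  s0 <- signature_score(m, null_genes, seed = 5)
  expect_lt(abs(mean(s0)), 0.05)
  # multiplying signature counts in one cell strictly increases its score
  m2 <- m
  m2[null_genes, 1] <- m2[null_genes, 1] * 10 + 5
  s1 <- signature_score(m2, null_genes, seed = 5)
  expect_gt(s1[1], s0[1])
  # deterministic for a fixed seed
  expect_equal(s0, signature_score(m, null_genes, seed = 5))
  expect_error(signature_score(m, c("absent1", "absent2")),
               "no signature gene")
})

test_that("PC-state cells outscore B cells on the PC marker signature", {
  ex <- expr_fixture()
  pc_sig <- ex$marker_map[["PC-Tigit"]]
  s <- signature_score(ex$counts, pc_sig, seed = 2)
  st <- truth_lookup(ex$truth, "state")[names(s)]
  pc <- s[st == "PC-Tigit"]
  bcell <- s[st %in% c("B-naive", "B-MZ", "B-activated")]
  wt <- stats::wilcox.test(pc, bcell, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("frequency decomposition is exact on constructed mixtures", {
  # pinned arithmetic: (0.6,0.4) - 0.5*(1.0,0.0) -> (0.1,0.4) -> (0.2,0.8)
  got <- subset_frequency_decomposition(c(a = 0.6, b = 0.4),
                                        c(a = 1.0, b = 0.0), alpha = 0.5)
  expect_equal(unname(got), c(0.2, 0.8))
  # alpha = 0 returns the mixed fractions unchanged
  f <- c(a = 0.3, b = 0.7)
  expect_equal(subset_frequency_decomposition(f, c(a = 0.5, b = 0.5), 0), f)
  # algebraic recovery: f_mixed = (1-a) f_target + a f_pure
  set.seed(23)
  for (i in 1:100) {
    k <- sample(3:8, 1)
    f_target <- as.numeric(rmultinom(1, 1000, runif(k))) / 1000
    f_pure <- as.numeric(rmultinom(1, 1000, runif(k))) / 1000
    a <- runif(1, 0, 0.95)
    names(f_target) <- names(f_pure) <- paste0("s", seq_len(k))
    f_mixed <- (1 - a) * f_target + a * f_pure
    rec <- subset_frequency_decomposition(f_mixed, f_pure, alpha = a)
    expect_lt(max(abs(rec - f_target)), 1e-12)
  }
  expect_error(
    subset_frequency_decomposition(c(a = 1, b = 0), c(a = 1, b = 0), 1),
    "degenerate")
})

test_that("identical groups produce zero differentially expressed genes", {
  ex <- expr_fixture()
  m <- ex$counts[, 1:40]
  deg <- differential_expression(m, m)
  expect_equal(sum(deg$is_deg), 0L)
  expect_true(all(deg$abs_fold >= 1))
  expect_error(differential_expression(m[, 1:2], m), ">= 3 cells")
})

test_that("sub-threshold fold is never called significant", {
  # gene with tiny p but absolute fold 1.1 must not pass the 1.2 gate
  set.seed(41)
  n <- 200
  a <- matrix(rpois(50 * n, 20), nrow = 50)
  b <- matrix(rpois(50 * n, 20), nrow = 50)
  b[1, ] <- rpois(n, 22)  # fold ~1.1 with huge n -> small p
  rownames(a) <- rownames(b) <- paste0("g", 1:50)
  libs <- c(colSums(a), colSums(b))
  deg <- differential_expression(Matrix::Matrix(a, sparse = TRUE),
                                 Matrix::Matrix(b, sparse = TRUE),
                                 target = median(libs))
  g1 <- deg[deg$gene == "g1", ]
  expect_lt(g1$abs_fold, 1.2)
  expect_false(g1$is_deg)
})

test_that("planted fold changes are recovered with controlled FDR", {
  set.seed(19)
  n_genes <- 800; n <- 60
  base <- rgamma(n_genes, 2, 0.1)
  a <- matrix(rpois(n_genes * n, base), nrow = n_genes)
  mu_b <- base
  planted <- sample(n_genes, 15)
  mu_b[planted] <- mu_b[planted] * 2
  b <- matrix(rpois(n_genes * n, mu_b), nrow = n_genes)
  rownames(a) <- rownames(b) <- paste0("g", seq_len(n_genes))
  deg <- differential_expression(Matrix::Matrix(a, sparse = TRUE),
                                 Matrix::Matrix(b, sparse = TRUE))
  hits <- which(deg$is_deg)
  expect_gte(sum(hits %in% planted), 12)
  fdp <- if (length(hits)) mean(!(hits %in% planted)) else 0
  expect_lte(fdp, 0.2)
})

test_that("moderated t agrees with the limma cross-check", {
  skip_if_not_installed("limma")
  set.seed(29)
  n_genes <- 300; n <- 20
  a <- matrix(rpois(n_genes * n, 30), nrow = n_genes)
  b <- matrix(rpois(n_genes * n, 30), nrow = n_genes)
  b[1:10, ] <- matrix(rpois(10 * n, 90), nrow = 10)
  rownames(a) <- rownames(b) <- paste0("g", seq_len(n_genes))
  libs <- c(colSums(a), colSums(b))
  deg <- differential_expression(Matrix::Matrix(a, sparse = TRUE),
                                 Matrix::Matrix(b, sparse = TRUE),
                                 target = median(libs))
  la <- as.matrix(lognorm(a, target = median(libs)))
  lb <- as.matrix(lognorm(b, target = median(libs)))
  design <- cbind(1, c(rep(1, n), rep(0, n)))
  fit <- limma::eBayes(limma::lmFit(cbind(la, lb), design))
  t_limma <- fit$t[, 2]
  expect_gt(cor(deg$t, t_limma), 0.999)
  # the same genes reach significance either way
  expect_equal(unname(which(deg$adj_p < 0.05)),
               unname(which(p.adjust(fit$p.value[, 2], "BH") < 0.05)))
})

test_that("chi-square state-frequency test matches the closed form", {
  # proportionally identical counts: chi2 = 0, p = 1
  r0 <- state_frequency_test(c(s1 = 50, s2 = 50), c(s1 = 100, s2 = 100))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p_value, 1)
  # pinned 2x2 value: (90,10)/(10,90), E = 50 everywhere
  brute <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  tab <- rbind(c(90, 10), c(10, 90))
  expect_equal(brute(tab), 128)
  r <- state_frequency_test(c(s1 = 90, s2 = 10), c(s1 = 10, s2 = 90))
  expect_equal(r$chi2, 128)
  expect_equal(r$df, 1)
  # symmetry under group swap
  r_swap <- state_frequency_test(c(s1 = 10, s2 = 90), c(s1 = 90, s2 = 10))
  expect_equal(r_swap$chi2, r$chi2)
  # zero-total states are dropped, reducing df
  expect_warning(
    r3 <- state_frequency_test(c(s1 = 30, s2 = 20, s3 = 0),
                               c(s1 = 25, s2 = 25, s3 = 0)), "dropping")
  expect_equal(r3$df, 1)
})

test_that("classification accuracy rises with marker fold", {
  accs <- vapply(c(2, 4, 8), function(mf) {
    cfg <- sim_config(n_cells = 270L, n_clones = 30L, n_genes = 400L,
                      n_marker_genes_per_state = 8L, marker_fold = mf,
                      library_size_mean = 600, seed = 77L)
    truth <- data.frame(
      barcode = sprintf("c%04d", 1:270),
      state = rep(names(cfg$state_proportions), each = 30),
      stringsAsFactors = FALSE)
    ex <- simulate_expression(truth, cfg)
    ref <- build_centroids(ex$counts, truth_lookup(truth, "state"),
                           unlist(ex$marker_map))
    cls <- classify_cells(ex$counts, ref)
    mean(cls$label == truth$state)
  }, 0)
  expect_true(all(diff(accs) >= 0))
  expect_gte(accs[3], 0.95)
})
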