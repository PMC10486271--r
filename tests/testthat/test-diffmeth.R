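make_beta <- function(rows, ids = sprintf("s%02d", seq_len(ncol(rows)))) {
  colnames(rows) <- ids
  rows
}

two_group_samples <- function(n0, n1) {
  data.frame(sample_id = sprintf("s%02d", seq_len(n0 + n1)),
             phenotype = rep(c("NT", "I"), c(n0, n1)),
             stringsAsFactors = FALSE)
}

test_that("mean difference and tumor mean are plain arithmetic", {
  beta <- make_beta(rbind(cg1 = c(0.8, 0.9, 0.1, 0.2)))
  dm <- dm_test(beta, two_group_samples(2, 2), "NT", "I")
  expect_equal(dm$mean_diff, -0.7)
  expect_equal(dm$tumor_mean_beta, 0.15)
})

test_that("exact Wilcoxon p matches the [1,2,3] vs [4,5,6] enumeration", {
  beta <- make_beta(rbind(cg1 = c(4, 5, 6, 1, 2, 3) / 10))
  dm <- dm_test(beta, two_group_samples(3, 3), "NT", "I")
  expect_equal(dm$pvalue, 0.1)  # 2 * (1 / C(6,3)) * ... = 0.1 by enumeration
  expect_equal(dm$pvalue, wilcox_enum_p(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6)))
})

test_that("exact Wilcoxon p equals full enumeration for all group sizes <= 6", {
  set.seed(11)
  for (n1 in 2:6) for (n2 in 2:6) {
    x <- runif(n1) + 0.3 * (n1 %% 2)
    y <- runif(n2)
    expect_equal(mdgpipe:::rank_sum_p(x, y), wilcox_enum_p(x, y),
                 info = paste(n1, n2))
  }
})

test_that("the normal-approximation path matches wilcox.test with ties", {
  set.seed(12)
  for (i in 1:10) {
    x <- sample(seq_len(8), 15, replace = TRUE) / 10  # heavy ties
    y <- sample(seq_len(8), 20, replace = TRUE) / 10 + 0.05 * (i %% 2)
    expect_equal(mdgpipe:::rank_sum_p(x, y),
                 suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("status requires the mean-diff cutoff, p-value and beta band together", {
  sam <- two_group_samples(10, 10)
  # large shift landing outside the band -> called
  hi <- make_beta(rbind(cg1 = c(rep(0.2, 10), rep(0.8, 10))))
  expect_identical(dm_test(hi, sam, "NT", "I")$status, "hyper")
  lo <- make_beta(rbind(cg1 = c(rep(0.8, 10), rep(0.2, 10))))
  expect_identical(dm_test(lo, sam, "NT", "I")$status, "hypo")
  # significant but small shift (0.10 < 0.15) -> none
  small <- make_beta(rbind(cg1 = c(rep(0.60, 10), rep(0.70, 10))))
  out <- dm_test(small, sam, "NT", "I")
  expect_lt(out$pvalue, 0.05)
  expect_identical(out$status, "none")
  # big shift but tumor mean inside the band -> none unless band disabled
  mid <- make_beta(rbind(cg1 = c(rep(0.15, 10), rep(0.5, 10))))
  expect_identical(dm_test(mid, sam, "NT", "I")$status, "none")
  expect_identical(dm_test(mid, sam, "NT", "I", band = FALSE)$status, "hyper")
  # constant CpG -> p = 1, none
  const <- make_beta(rbind(cg1 = rep(0.5, 20)))
  out <- dm_test(const, sam, "NT", "I")
  expect_equal(out$pvalue, 1)
  expect_identical(out$status, "none")
})

test_that("swapping groups negates mean_diff and swaps hypo/hyper calls", {
  set.seed(13)
  beta <- make_beta(rbind(
    up = c(runif(10, 0.1, 0.3), runif(10, 0.7, 0.9)),
    down = c(runif(10, 0.7, 0.9), runif(10, 0.1, 0.3)),
    flat = runif(20, 0.4, 0.6)))
  sam <- two_group_samples(10, 10)
  a <- dm_test(beta, sam, "NT", "I", band = FALSE)
  b <- dm_test(beta, sam, "I", "NT", band = FALSE)
  expect_equal(a$mean_diff, -b$mean_diff)
  expect_equal(a$pvalue, b$pvalue)
  swap <- c(hyper = "hypo", hypo = "hyper", none = "none")
  expect_identical(unname(swap[a$status]), b$status)
})

test_that("a degenerate bootstrap reproduces the plain dm_test counts", {
  co <- simulate_cohort(small_config(seed = 15, n_genes = 40))
  beta <- clean_cpgs(co$beta)
  plain <- dm_test(beta, co$samples, "NT", "I")
  boot <- bootstrap_dm_counts(beta, co$samples, list(c("NT", "I")),
                              n_boot = 1, group_size = 24, seed = 1)
  expect_equal(boot$hyper_mean, sum(plain$status == "hyper"))
  expect_equal(boot$hypo_mean, sum(plain$status == "hypo"))
})

test_that("bootstrap recovers planted differentially methylated CpG counts", {
  # 100 planted hypo CpGs (NT 0.85 -> tumor 0.35) among 100 null CpGs
  set.seed(16)
  n0 <- 30; n1 <- 40
  sam <- data.frame(sample_id = sprintf("s%02d", 1:(n0 + n1)),
                    phenotype = rep(c("NT", "I"), c(n0, n1)))
  planted <- t(sapply(1:100, function(i)
    c(rbeta(n0, 0.85 * 50, 0.15 * 50), rbeta(n1, 0.35 * 50, 0.65 * 50))))
  nulls <- t(sapply(1:100, function(i) rbeta(n0 + n1, 0.2 * 50, 0.8 * 50)))
  beta <- rbind(planted, nulls)
  rownames(beta) <- sprintf("cg%03d", 1:200)
  colnames(beta) <- sam$sample_id
  boot <- bootstrap_dm_counts(beta, sam, list(c("NT", "I")), n_boot = 50,
                              group_size = 24, seed = 2)
  expect_gte(boot$hypo_mean, 90)
  expect_lte(boot$hypo_mean, 100)
  # reproducible given the seed
  boot2 <- bootstrap_dm_counts(beta, sam, list(c("NT", "I")), n_boot = 50,
                               group_size = 24, seed = 2)
  expect_identical(boot, boot2)
})

test_that("sample clustering separates disjoint beta supports perfectly", {
  set.seed(17)
  beta <- cbind(matrix(runif(200, 0, 0.2), 40, 5),
                matrix(runif(200, 0.8, 1), 40, 5))
  rownames(beta) <- paste0("cg", 1:40)
  colnames(beta) <- paste0("s", 1:10)
  sam <- data.frame(sample_id = colnames(beta),
                    phenotype = rep(c("NT", "I"), each = 5))
  out <- cluster_samples(beta, sam)
  expect_equal(out$nt_purity, 1)
})

test_that("a planted NT-wide methylation shift yields high NT cluster purity", {
  set.seed(18)
  n_cpg <- 200; n_nt <- 12; n_tu <- 30
  base <- rbeta(n_cpg, 2, 2)
  mk <- function(n, means) sapply(1:n, function(i) rbeta(n_cpg, means * 30, (1 - means) * 30))
  shift_idx <- sample(n_cpg, 60)  # 30% of CpGs shifted in NT
  means_nt <- base; means_nt[shift_idx] <- pmin(base[shift_idx] + 0.3, 0.95)
  beta <- cbind(mk(n_nt, means_nt), mk(n_tu, base))
  rownames(beta) <- paste0("cg", 1:n_cpg)
  colnames(beta) <- paste0("s", 1:(n_nt + n_tu))
  sam <- data.frame(sample_id = colnames(beta),
                    phenotype = rep(c("NT", "I"), c(n_nt, n_tu)))
  expect_gte(cluster_samples(beta, sam)$nt_purity, 0.95)
})

test_that("randomly permuted labels give purity near the majority fraction", {
  set.seed(19)
  beta <- matrix(rbeta(300 * 20, 2, 2), 300, 20,
                 dimnames = list(paste0("cg", 1:300), paste0("s", 1:20)))
  purities <- replicate(20, {
    sam <- data.frame(sample_id = paste0("s", 1:20),
                      phenotype = sample(rep(c("NT", "I"), each = 10)))
    cluster_samples(beta, sam)$nt_purity
  })
  # with exchangeable columns the NT majority-cluster fraction concentrates
  # around the larger cluster's share; it must not sit near 1
  expect_lt(mean(purities), 0.95)
  expect_gt(mean(purities), 0.4)
})
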