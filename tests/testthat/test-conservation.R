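# exhaustive two-sided Fisher oracle from explicit binomial coefficients
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  as <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- choose(r1, as) * choose(n - r1, c1 - as) / choose(n, c1)
  min(1, sum(pr[pr <= pr[match(a, as)] * (1 + 1e-7)]))
}

test_that("two-sided Fisher p agrees with enumeration and fisher.test", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(4:60, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    c <- sample(0:(n - a - b), 1); d <- n - a - b - c
    p <- fisher_exact_2x2(a, b, c, d)
    expect_equal(p, fisher_enum_oracle(a, b, c, d), tolerance = 1e-12)
    expect_equal(p, fisher.test(matrix(c(a, c, b, d), 2))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("median dN/dS resampling detects a planted conserved stage", {
  set.seed(7)
  n_bg <- 2000
  ids <- sprintf("g%04d", 1:n_bg)
  dn <- rlnorm(n_bg, -1.5, 0.5)
  stage <- sample(ids, 200)
  dn[match(stage, ids)] <- rlnorm(200, -2.5, 0.5)
  annot <- flat_annot(ids, dnds = dn)
  res <- median_dnds_test(stage, annot, n_perm = 2000, seed = 42)
  expect_lte(res$p_value, 0.05)
  expect_lt(res$observed_median, res$ci_low)
  expect_equal(res$direction, "lower")
  # same seed reproduces exactly; a different seed moves p by MC error only
  res2 <- median_dnds_test(stage, annot, n_perm = 2000, seed = 42)
  expect_identical(res$p_value, res2$p_value)
  expect_identical(c(res$ci_low, res$ci_high), c(res2$ci_low, res2$ci_high))
})

test_that("degenerate resampling cases behave as defined", {
  ids <- sprintf("g%03d", 1:300)
  annot <- flat_annot(ids, dnds = rlnorm(300, -1.5, 0.5))
  # stage = entire background: observed equals background median, p ~ 1
  res <- median_dnds_test(ids, annot, n_perm = 500, seed = 1)
  expect_equal(res$observed_median, res$background_median)
  expect_gte(res$p_value, 0.9)
  # tiny stage set: unreliable, no p
  small <- median_dnds_test(ids[1:3], annot, n_perm = 100, seed = 1)
  expect_false(small$reliable)
  expect_true(is.na(small$p_value))
})

test_that("a larger planted shift never weakens the resampling p", {
  set.seed(12)
  ids <- sprintf("g%04d", 1:1500)
  base <- rlnorm(1500, -1.5, 0.5)
  stage <- ids[1:150]
  ps <- vapply(c(0, 0.4, 0.8, 1.2), function(shift) {
    dn <- base
    dn[1:150] <- base[1:150] * exp(-shift)
    median_dnds_test(stage, flat_annot(ids, dnds = dn),
                     n_perm = 1000, seed = 99)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("category enrichment matches hand-built 2x2 tables", {
  ids <- sprintf("g%03d", 1:100)
  age <- rep(age_intervals(), times = c(50, 25, 15, 10))
  annot <- flat_annot(ids, age = age)
  # stage proportions identical to background: obs - exp = 0, p = 1
  stage <- c(ids[1:10], ids[51:55], ids[76:78], ids[91:92])
  res <- category_enrichment(stage, annot, "age_interval")
  expect_equal(res$obs_minus_exp, rep(0, 4))
  expect_equal(res$p_value, rep(1, 4), tolerance = 1e-12)
  # table (8,2,10,80) against the enumeration oracle
  ids2 <- sprintf("h%03d", 1:100)
  cat2 <- rep(c("Mammalia-Eutheria", "Opisthokonta-Bilateria"), c(18, 82))
  annot2 <- flat_annot(ids2, age = cat2)
  stage2 <- c(ids2[1:8], ids2[19:20])   # 8 in category of 18, stage size 10
  res2 <- category_enrichment(stage2, annot2, "age_interval",
                              categories = "Mammalia-Eutheria")
  expect_equal(res2$observed_count, 8L)
  expect_equal(res2$p_value, fisher_enum_oracle(8, 2, 10, 80),
               tolerance = 1e-12)
  expect_equal(res2$obs_minus_exp, 8 / 10 - 18 / 100)
  expect_error(category_enrichment(c("zzz"), annot, "age_interval"),
               "no stage gene")
})

test_that("planted category excess is flagged over-represented", {
  set.seed(15)
  n <- 2000
  ids <- sprintf("g%04d", 1:n)
  cls <- ifelse(runif(n) < 0.15, "new_gene", "one2one")
  stage_idx <- 1:300
  cls[stage_idx] <- ifelse(runif(300) < 0.35, "new_gene", "one2one")
  annot <- flat_annot(ids, ortho = cls)
  res <- category_enrichment(ids[stage_idx], annot, "ortholog_class",
                             categories = "new_gene")
  expect_lt(res$p_value, 0.01)
  expect_equal(res$direction, "over")
  expect_true(res$significant)
})

test_that("obs-minus-exp sums to zero over a partition", {
  set.seed(16)
  ids <- sprintf("g%04d", 1:800)
  age <- sample(age_intervals(), 800, replace = TRUE)
  ort <- sample(c("one2one", "one2many", "many2many", "new_gene"), 800,
                replace = TRUE, prob = c(0.5, 0.25, 0.1, 0.15))
  annot <- flat_annot(ids, age = age, ortho = ort)
  stage <- sample(ids, 120)
  res_a <- category_enrichment(stage, annot, "age_interval")
  expect_lt(abs(sum(res_a$obs_minus_exp)), 1e-12)
  res_o <- category_enrichment(stage, annot, "ortholog_class",
                               exclude_categories = "many2many")
  expect_identical(sort(res_o$category),
                   sort(c("one2one", "one2many", "new_gene")))
  expect_lt(abs(sum(res_o$obs_minus_exp)), 1e-12)
})

test_that("TF/HCNE hypergeometric test matches the closed form", {
  ids <- sprintf("g%02d", 1:50)
  annot <- flat_annot(ids, tf = rep(c(TRUE, FALSE), each = 25))
  stage <- ids[1:10]    # all flagged, background 50% flagged
  res <- tf_hcne_enrichment(stage, annot, "is_tf")
  expect_equal(res$p_value, choose(25, 10) / choose(50, 10),
               tolerance = 1e-12)
  expect_equal(res$observed_count, 10L)
  # stage at background rate is unremarkable
  stage2 <- c(ids[1:5], ids[26:30])
  res2 <- tf_hcne_enrichment(stage2, annot, "is_tf")
  expect_gte(res2$p_value, 0.5)
  expect_false(res2$significant)
  # empty flag in background: p = 1 by convention
  annot0 <- flat_annot(ids, hcne = rep(FALSE, 50))
  expect_equal(tf_hcne_enrichment(stage, annot0, "has_hcne")$p_value, 1)
})

test_that("term enrichment applies Bonferroni over tested terms", {
  ids <- sprintf("g%03d", 1:110)
  stage <- ids[1:10]
  tt <- rbind(
    data.frame(gene_id = ids, term = "T_all"),
    data.frame(gene_id = stage, term = "T_hit"),
    data.frame(gene_id = ids[seq(1, 110, 11)], term = "T_flat"))
  res <- term_enrichment(stage, tt, alpha = 0.01)
  expect_true("T_hit" %in% res$term)
  expect_false("T_flat" %in% res$term)
  # closed form: all 10 stage genes in a 10-gene term, 3 tested terms
  p_raw <- 1 / choose(110, 10) * choose(100, 0) * choose(10, 10)
  expect_equal(res$p_value[res$term == "T_hit"],
               choose(10, 10) * choose(100, 0) / choose(110, 10),
               tolerance = 1e-10)
  expect_equal(res$p_bonferroni[res$term == "T_hit"],
               res$p_value[res$term == "T_hit"] * 3, tolerance = 1e-10)
  # raw p 0.004 with 5 terms -> corrected 0.02, excluded at alpha 0.01
  expect_equal(min(1, 0.004 * 5), 0.02)
})

test_that("trend summary encodes run-length sign patterns", {
  mk <- function(med) data.frame(stage = ped_stages(), observed_median = med)
  expect_equal(conservation_trend(mk(seq(0.3, 0.1, length.out = 7)))$
                 pattern_label, "up")
  expect_equal(conservation_trend(mk(rep(0.2, 7)))$pattern_label, "flat")
  shaped <- c(0.30, 0.22, 0.17, 0.12, 0.22, 0.16, 0.12)
  tr <- conservation_trend(mk(shaped))
  expect_equal(tr$pattern_label, "up-down-up")
  expect_equal(unname(tr$conservation_score), -shaped)
  expect_length(tr$direction_changes, 6L)
  expect_error(conservation_trend(mk(shaped)[-3, ]), "2cell")
})
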