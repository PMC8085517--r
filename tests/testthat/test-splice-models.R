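test_that("donor and acceptor windows follow the 3+6 / 20+3 conventions", {
  seqs <- paste0("AAAAAAAAAACAG", "GTAAGT", random_seq(30))
  set.seed(2)
  d <- extract_window(seqs, 13, "donor")
  expect_equal(d$seq, "CAGGTAAGT")
  expect_equal(nchar(d$seq), 9L)
  intronic <- paste0(random_seq(18), "AG")
  acc_seq <- paste0(intronic, "ATGCCC")
  a <- extract_window(acc_seq, 21, "acceptor")
  expect_equal(nchar(a$seq), 23L)
  expect_equal(substr(a$seq, 19, 20), "AG")
  expect_equal(substr(a$seq, 21, 23), "ATG")
  expect_error(extract_window("ACGTACGT", 2, "donor"), "too close")
})

test_that("annotated-junction windows are strand symmetric", {
  gp <- hand_gene("+"); gm <- hand_gene("-")
  # same gene-direction locus, so windows must be identical strings
  for (kind in c("donor", "acceptor")) {
    idx <- if (kind == "donor") 1:2 else 2:3
    for (j in idx) {
      expect_equal(extract_window(gp, j, kind)$seq,
                   extract_window(gm, j, kind)$seq,
                   info = sprintf("%s exon %d", kind, j))
    }
  }
  expect_equal(extract_window(gp, 1, "donor")$seq, "ATTGTAAGT")
})

test_that("PWM estimates follow the pseudocounted counting formula", {
  m <- train_wmm(c("GT", "GT"), pseudocount = 0)
  expect_equal(unname(m$p[1, "G"]), 1)
  expect_equal(unname(m$p[2, "T"]), 1)
  m2 <- train_wmm(c("GT", "GA"), pseudocount = 0)
  expect_equal(unname(m2$p[2, "T"]), 0.5)
  m3 <- train_wmm(c("GT", "GA"), pseudocount = 1)
  expect_equal(unname(m3$p[1, "G"]), 3 / 6)
  expect_equal(unname(m3$p[1, "A"]), 1 / 6)
  expect_error(train_wmm(c("GT", "GTA")), "mixed lengths")
  expect_true(all(abs(rowSums(m3$p) - 1) < 1e-9))
})

test_that("PWM scores are summed log2 odds with expected special cases", {
  m <- train_wmm(c("GT", "GT"), pseudocount = 0)
  expect_equal(score_wmm(m, "GT"), 4.0)
  # model equal to background everywhere scores 0
  flat <- train_wmm(all_kmers(2), pseudocount = 0)
  for (w in c("AA", "GT", "CG")) expect_equal(score_wmm(flat, w), 0)
  expect_error(score_wmm(m, "GTA"), "length")
})

test_that("the training consensus outscores every single-base variant", {
  set.seed(21)
  train <- c("CAGGTAAGT", "AAGGTAAGT", "CAGGTGAGT", "CTGGTAAGT",
             "CAGGTAATT", "GAGGTAAGA")
  m <- train_wmm(train, pseudocount = 1)
  cons <- paste0(colnames(m$p)[apply(m$p, 1, which.max)], collapse = "")
  s0 <- score_wmm(m, cons)
  for (i in 1:9) for (b in c("A", "C", "G", "T")) {
    w <- cons
    substr(w, i, i) <- b
    expect_lte(score_wmm(m, w), s0 + 1e-12)
  }
})

test_that("consensus values hit 100/0 at the consensus/anti-consensus and match a naive recomputation", {
  set.seed(33)
  for (kind in c("donor", "acceptor")) {
    fm <- ss_frequency_matrix(kind)
    cons <- paste0(colnames(fm)[apply(fm, 1, which.max)], collapse = "")
    anti <- paste0(colnames(fm)[apply(fm, 1, which.min)], collapse = "")
    expect_equal(ss_percent(cons, kind = kind), 100)
    expect_equal(ss_percent(anti, kind = kind), 0)
    for (i in 1:10) {
      w <- random_seq(nrow(fm))
      expect_equal(ss_percent(w, kind = kind), oracle_ss_percent(w, fm))
    }
  }
})

test_that("Markov training matches hand counting and degenerates to uniform", {
  m <- train_mm1(c("AAG", "AAG"), pseudocount = 0)
  expect_equal(unname(m$p1["A"]), 1)
  expect_equal(m$t[[1]]["A", "A"], 1)
  expect_equal(m$t[[2]]["A", "G"], 1)
  u <- train_mm1(all_kmers(3), pseudocount = 0)
  for (t_i in u$t) expect_true(all(abs(t_i - 0.25) < 1e-12))
  # pseudocounted hand arithmetic on a 3-sequence set
  h <- train_mm1(c("ACG", "ACG", "ATG"), pseudocount = 1)
  expect_equal(unname(h$p1["A"]), (3 + 1) / (3 + 4))
  expect_equal(h$t[[1]]["A", "C"], (2 + 1) / (3 + 4))
  expect_equal(h$t[[1]]["A", "T"], (1 + 1) / (3 + 4))
  expect_equal(h$t[[2]]["C", "G"], (2 + 1) / (2 + 4))
  expect_error(train_mm1(c("AC", "ACG")), "mixed lengths")
})

test_that("Markov scores are log2 odds and the model is a distribution", {
  m <- train_mm1(c("AAG", "AAG"), pseudocount = 0)
  expect_equal(score_mm1(m, "AAG"), 6.0)
  # a background-shaped model scores 0 everywhere
  flat <- train_mm1(all_kmers(3), pseudocount = 0)
  for (w in c("AAA", "ACG", "TTT")) expect_equal(score_mm1(flat, w), 0)
  # probabilities over all windows sum to 1 for L = 3, 4
  set.seed(9)
  for (L in 3:4) {
    train <- replicate(5, random_seq(L))
    mod <- train_mm1(train, pseudocount = 1)
    tot <- sum(vapply(all_kmers(L),
                      function(w) pseudoexonr:::prob_mm1(mod, w),
                      numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("maximum entropy with no constraints is uniform", {
  me <- fit_maxent(c("ACG", "TTA"), constraint_subsets = list())
  expect_equal(me$p, rep(1 / 64, 64))
  expect_true(me$converged)
})

test_that("singleton-constrained maximum entropy equals the PWM", {
  set.seed(10)
  train <- replicate(20, random_seq(5))
  me <- fit_maxent(train, constraint_subsets = as.list(1:5),
                   pseudocount = 1, tolerance = 1e-10)
  wm <- train_wmm(train, pseudocount = 1)
  d <- vapply(all_kmers(5),
              function(w) abs(score_maxent(me, w) - score_wmm(wm, w)),
              numeric(1))
  expect_lt(max(d), 1e-6)
})

test_that("fitted maximum-entropy marginals match their targets", {
  set.seed(11)
  train <- replicate(30, random_seq(4))
  me <- fit_maxent(train, pseudocount = 1, tolerance = 1e-8)
  expect_true(me$converged)
  expect_lt(me$max_dev, 1e-6)
  expect_equal(sum(me$p), 1, tolerance = 1e-9)
  # check one pair marginal independently
  S <- pseudoexonr:::state_matrix(4)
  idx <- pseudoexonr:::state_index(S[, c(1, 3)])
  got <- as.numeric(rowsum(me$p, idx))
  want <- pseudoexonr:::empirical_marginal(
    pseudoexonr:::windows_to_matrix(train), c(1, 3), 1)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("a fully constrained toy reproduces the empirical table", {
  me <- fit_maxent(c("AC", "AC", "GT"), constraint_subsets = list(c(1, 2)),
                   pseudocount = 0, tolerance = 1e-12)
  p_ac <- me$p[pseudoexonr:::state_index(matrix(c(1, 2), 1))]
  p_gt <- me$p[pseudoexonr:::state_index(matrix(c(3, 4), 1))]
  expect_equal(p_ac, 2 / 3, tolerance = 1e-9)
  expect_equal(p_gt, 1 / 3, tolerance = 1e-9)
})

test_that("maximum-entropy limits and invalid constraints are enforced", {
  expect_error(fit_maxent(replicate(3, random_seq(10))), "length <= 9")
  expect_error(fit_maxent(c("ACG"), constraint_subsets = list(c(1, 5))),
               "invalid window positions")
  expect_equal(score_maxent(fit_maxent(c("AC", "GT"),
                                       constraint_subsets = list()),
                            "AC"), 0)
})

test_that("external score tables are looked up verbatim", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("seq\tscore", "CAGGTAAGT\t8.77", "ATGGTAAGT\t11.08"), path)
  tab <- load_maxent_score_table(path, "donor")
  expect_equal(score_maxent(tab, "ATGGTAAGT"), 11.08)
  expect_equal(score_maxent(tab, splice_window("donor", "cagGtaagt")), 8.77)
  expect_error(score_maxent(tab, "CCCGTAAGT"), "absent")
})

test_that("model training is deterministic for identical inputs", {
  set.seed(3); train1 <- replicate(15, random_seq(5))
  w1 <- train_wmm(train1); w2 <- train_wmm(train1)
  expect_identical(w1$p, w2$p)
  m1 <- train_mm1(train1); m2 <- train_mm1(train1)
  expect_identical(m1$t, m2$t)
  e1 <- fit_maxent(train1); e2 <- fit_maxent(train1)
  expect_identical(e1$p, e2$p)
})

test_that("score panels report deltas, pass external scores through, and serialize", {
  ref <- splice_window("donor", "CAGCTAAGT")   # broken GT
  mut <- splice_window("donor", "CAGGTAAGT", mutated_pos = 4)
  set.seed(14)
  train <- c("CAGGTAAGT", "AAGGTAAGT", "CAGGTGAGT", "ATGGTAAGT",
             "CAGGTAATT", "AAGGTAAGA")
  models <- list(wmm = train_wmm(train), mm1 = train_mm1(train),
                 maxent = fit_maxent(train, constraint_subsets = as.list(1:9)))
  same <- score_panel(mut, mut, models = models)
  expect_true(all(same$delta[same$source == "computed"] == 0))
  panel <- score_panel(ref, mut, models = models,
                       external_scores = c(spliceai_donor_gain = 0.75))
  expect_true(all(panel$delta[panel$metric %in%
                                c("wmm_logodds", "mm1_logodds",
                                  "maxent_logodds")] > 0))
  ext <- panel[panel$metric == "spliceai_donor_gain", ]
  expect_equal(ext$mutant, 0.75)
  expect_equal(ext$source, "external:recommended")
  expect_error(score_panel(ref, splice_window("acceptor",
                                              random_seq(23))),
               "different kinds")
  # serialization round-trips losslessly
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(panel, path, digits = NA, na = "null")
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$metric, panel$metric)
  expect_equal(back$reference, panel$reference, tolerance = 1e-12)
  expect_equal(back$delta, panel$delta, tolerance = 1e-12)
})

test_that("deep-network gain scores map onto the conventional bands", {
  expect_equal(spliceai_band(c(0.1, 0.2, 0.47, 0.5, 0.9)),
               c("below-high-recall", "high-recall", "high-recall",
                 "recommended", "high-precision"))
})
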