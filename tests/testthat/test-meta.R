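test_that("load_scores joins score files onto the structure residue order", {
  ag <- make_synthetic_antigen(fixture_spec(n_residues = 25, n_patches = 1,
                                            patch_size = 6, seed = 2), "j")
  dir <- tempfile(); dir.create(dir)
  tab0 <- simulate_scores(ag, dir = dir, label = FALSE)
  paths <- attr(tab0, "paths")

  tab <- load_scores(paths, ag$structure)
  expect_s3_class(tab, "score_table")
  expect_equal(nrow(tab), 25)
  for (cl in score_classifiers(tab)) expect_equal(tab[[cl]], tab0[[cl]])

  # a file missing residues imputes 0 with a warning
  short <- read_score_tsv(paths[1])[-c(3, 7), ]
  write_score_tsv(short, paths[1])
  expect_warning(tab2 <- load_scores(paths, ag$structure), "imputed")
  expect_equal(tab2[[score_classifiers(tab2)[1]]][c(3, 7)], c(0, 0))

  # no residue overlap at all is an error
  bogus <- data.frame(chain = "Z", seqnum = 900:905, icode = "",
                      score = 0.5)
  write_score_tsv(bogus, paths[2])
  expect_error(suppressWarnings(load_scores(paths, ag$structure)),
               "no residues")
})

test_that("load_scores matches residues with insertion codes exactly", {
  st <- structure_from_xyz(matrix(rnorm(9), 3, 3))
  st$residues$icode <- c("", "A", "B")
  st$residues$seqnum <- c(10L, 10L, 10L)
  f <- tempfile(fileext = ".tsv")
  # hand-built table: out of order, scores keyed by icode
  write_score_tsv(data.frame(chain = "A", seqnum = 10L,
                             icode = c("B", "", "A"),
                             score = c(0.3, 0.1, 0.2)), f)
  tab <- load_scores(c(clf = f), st)
  expect_equal(tab$clf, c(0.1, 0.2, 0.3))
})

test_that("normalize_scores rescales per classifier and is idempotent", {
  tab <- epimeta:::new_score_table(
    data.frame(antigen_id = "x", chain = "A", seqnum = 1:3, icode = "",
               c1 = c(2, 4, 6), c2 = c(0, 0.25, 1), c3 = c(0.7, 0.7, 0.7)),
    classifiers = c("c1", "c2", "c3"))
  expect_warning(norm <- normalize_scores(tab), "constant")
  expect_equal(norm$c1, c(0, 0.5, 1))
  expect_equal(norm$c2, c(0, 0.25, 1))   # already spanning [0,1]: unchanged
  expect_equal(norm$c3, c(0, 0, 0))
  expect_equal(normalize_scores(norm)$c1, norm$c1)  # idempotent

  # per-antigen normalisation is independent across antigens
  two <- epimeta:::new_score_table(
    data.frame(antigen_id = rep(c("x", "y"), each = 2), chain = "A",
               seqnum = 1:4, icode = "", c1 = c(1, 3, 10, 30)),
    classifiers = "c1")
  expect_equal(normalize_scores(two)$c1, c(0, 1, 0, 1))
})

test_that("make_folds partitions antigens with balanced sizes and strata", {
  sizes <- setNames(sample(100:450, 8), paste0("a", 1:8))
  fs <- make_folds(sizes, n_folds = 3, seed = 1)
  expect_equal(lengths(c(list(fs$test), fs$training)), rep(2L, 4),
               ignore_attr = TRUE)
  all_ids <- c(fs$test, unlist(fs$training))
  expect_setequal(all_ids, names(sizes))
  expect_equal(anyDuplicated(all_ids), 0L)

  # stratification: every group's tertile composition is within one
  # antigen of the proportional share
  set.seed(99)
  sizes2 <- setNames(sample(80:450, 60, replace = TRUE), paste0("g", 1:60))
  fs2 <- make_folds(sizes2, n_folds = 3, seed = 7)
  asn <- fs2$assignment
  for (g in unique(asn$group)) {
    ng <- sum(asn$group == g)
    for (t in 1:3) {
      expected <- ng * sum(asn$tertile == t) / nrow(asn)
      expect_lte(abs(sum(asn$group == g & asn$tertile == t) - expected), 1)
    }
  }
  # deterministic under a fixed seed
  expect_identical(make_folds(sizes2, seed = 7)$assignment,
                   fs2$assignment)
  expect_error(make_folds(sizes[1:3], n_folds = 3), "at least")
})

test_that("a perfectly informative feature is learned exactly", {
  set.seed(5)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  tab <- epimeta:::new_score_table(
    data.frame(antigen_id = "x", chain = "A", seqnum = 1:n, icode = "",
               perfect = y, noise = runif(n), label = y),
    classifiers = c("perfect", "noise"))
  m <- fit_meta(tab, config = meta_config(n_trees = 20))
  p <- predict(m, tab)
  expect_equal(roc_auc(p, y), 1)
  # all positives rank above all negatives
  expect_gt(min(p[y == 1]), max(p[y == 0]))
  # repeated prediction is bitwise identical
  expect_identical(p, predict(m, tab))
  # refitting is fully reproducible
  m2 <- fit_meta(tab, config = meta_config(n_trees = 20))
  expect_identical(p, predict(m2, tab))
})

test_that("pure-noise features give chance-level cross-validated AUC", {
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 300
    df <- data.frame(antigen_id = "x", chain = "A", seqnum = 1:n,
                     icode = "", f1 = runif(n), f2 = runif(n),
                     f3 = runif(n), label = rbinom(n, 1, 0.3))
    tab <- epimeta:::new_score_table(df, classifiers = c("f1", "f2", "f3"))
    half <- seq_len(n / 2)
    m <- fit_meta(tab[half, ], classifiers = c("f1", "f2", "f3"),
                  config = meta_config(n_trees = 40))
    roc_auc(predict(m, tab[-half, ]), df$label[-half])
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("integrating complementary features beats each one alone", {
  set.seed(17)
  n <- 400
  y <- rbinom(n, 1, 0.25)
  half <- seq_len(n) <= n / 2
  # each feature is informative on only one half of the data
  f1 <- ifelse(half, y * 0.8, 0) + rnorm(n, 0, 0.15)
  f2 <- ifelse(!half, y * 0.8, 0) + rnorm(n, 0, 0.15)
  df <- data.frame(antigen_id = rep(c("u", "v"), 2)[seq_len(n) %% 2 + 1],
                   chain = "A", seqnum = 1:n, icode = "",
                   f1 = f1, f2 = f2, label = y)
  tab <- epimeta:::new_score_table(df, classifiers = c("f1", "f2"))
  train <- seq_len(n) %% 4 < 2
  m <- fit_meta(tab[train, ], classifiers = c("f1", "f2"),
                config = meta_config(n_trees = 80))
  auc_meta <- roc_auc(predict(m, tab[!train, ]), y[!train])
  auc_single <- c(roc_auc(f1[!train], y[!train]),
                  roc_auc(f2[!train], y[!train]))
  expect_gte(auc_meta, max(auc_single))
})

test_that("a model on a single informative feature preserves its ranking", {
  set.seed(23)
  n <- 1000
  x <- runif(n)
  y <- rbinom(n, 1, plogis(12 * (x - 0.5)))
  tab <- epimeta:::new_score_table(
    data.frame(antigen_id = "x", chain = "A", seqnum = 1:n, icode = "",
               f = x, label = y),
    classifiers = "f")
  # regularised stumps: a single feature admits a near-monotone fit
  m <- fit_meta(tab, config = meta_config(n_trees = 100, max_depth = 1,
                                          lambda = 5))
  p <- predict(m, tab)
  expect_gte(cor(p, x, method = "kendall"), 0.9)
})

test_that("fit_meta validates inputs and predict checks features", {
  tab <- epimeta:::new_score_table(
    data.frame(antigen_id = "x", chain = "A", seqnum = 1:10, icode = "",
               f = runif(10), label = rep(1, 10)),
    classifiers = "f")
  expect_error(fit_meta(tab), "single class")
  tab$label <- NULL
  expect_error(fit_meta(tab), "label")

  tab$label <- rep(c(0, 1), 5)
  m <- fit_meta(tab, config = meta_config(n_trees = 5))
  expect_error(predict(m, data.frame(g = 1:3)), "feature")
})

test_that("hyperparameter tuning selects from the stated grid", {
  set.seed(31)
  n <- 240
  ids <- rep(paste0("ag", 1:6), each = n / 6)
  y <- rbinom(n, 1, 0.3)
  tab <- epimeta:::new_score_table(
    data.frame(antigen_id = ids, chain = "A", seqnum = 1:n, icode = "",
               f1 = y * 0.5 + runif(n, 0, 0.6), f2 = runif(n), label = y),
    classifiers = c("f1", "f2"))
  m <- fit_meta(tab, config = meta_config(n_trees = 20), tune = TRUE,
                depth_grid = c(2, 3), alpha_grid = c(0, 1),
                inner_folds = 2)
  expect_true(m$config$max_depth %in% c(2, 3))
  expect_true(m$config$alpha %in% c(0, 1))
  expect_equal(nrow(m$tuning), 4)
  expect_true(all(is.finite(m$tuning$auc)))
})
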