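# small separable feature table: two shifted Gaussian clouds; with
# `exact = TRUE` the first feature is a discrete class marker, so held-out
# points can never fall between a fold's decision cut and the class boundary
separable_table <- function(n_per_class = 100, p = 6, gap = 8, seed = 1,
                            exact = FALSE) {
  set.seed(seed)
  m <- rbind(
    matrix(rnorm(n_per_class * p), ncol = p),
    matrix(rnorm(n_per_class * p, mean = gap), ncol = p)
  )
  colnames(m) <- paste0("raw__f", seq_len(p))
  if (exact) m[, 1] <- rep(c(0, gap), each = n_per_class)
  out <- tibble::as_tibble(m)
  out$label <- rep(c("non-seizure", "seizure"), each = n_per_class)
  out
}

test_that("the classifier separates separable classes and is deterministic", {
  tab <- separable_table()
  cfg <- classifier_config(n_trees = 50, seed = 9)
  model <- fit_classifier(tab, cfg)
  expect_equal(mean(predict(model, tab) == tab$label), 1)

  model2 <- fit_classifier(tab, cfg)
  expect_identical(predict(model, tab), predict(model2, tab))

  single <- tab[tab$label == "seizure", ]
  expect_error(fit_classifier(single, cfg), "2 classes")
})

test_that("importance ranking is a normalized descending distribution", {
  tab <- separable_table(p = 10)
  ranking <- importance_ranking(fit_classifier(tab, classifier_config(n_trees = 40)))
  expect_equal(sum(ranking$score), 1, tolerance = 1e-9)
  expect_true(all(ranking$score >= 0))
  expect_true(all(diff(ranking$score) <= 1e-12))
  expect_equal(nrow(ranking), 10)
})

test_that("threshold selection keeps boundary scores and is monotone", {
  ranking <- tibble::tibble(
    feature = c("a", "b", "c", "d"),
    score = c(0.6, 0.399, 0.001, 0.0)
  )
  expect_equal(select_features(ranking, 0.001), c("a", "b", "c"))

  uniform <- tibble::tibble(feature = sprintf("f%03d", 1:100), score = rep(0.01, 100))
  expect_equal(length(select_features(uniform, 0.001)), 100)

  expect_error(select_features(ranking, 1.1), "lower the selection threshold")

  for (thr in c(0.0005, 0.01, 0.1, 0.5)) {
    low <- select_features(ranking, thr)
    higher <- tryCatch(select_features(ranking, thr * 2), error = function(e) character())
    expect_true(all(higher %in% low))
  }
})

test_that("top_features annotates component and domain, ties lexicographic", {
  ranking <- tibble::tibble(
    feature = c("imf_2__abs_energy", "raw__sample_entropy", "imf_1__abs_energy",
                "residue__mean"),
    score = c(0.4, 0.3, 0.2, 0.1)
  )
  top <- top_features(ranking, 3)
  expect_equal(nrow(top), 3)
  expect_equal(top$component, c("imf_2", "raw", "imf_1"))
  expect_equal(top$domain, c("time", "entropy", "time"))

  tied <- tibble::tibble(feature = c("b__mean", "a__mean"), score = c(0.5, 0.5))
  tied <- dplyr::arrange(tied, dplyr::desc(score), feature)
  expect_equal(top_features(tied, 1)$name, "a__mean")
  expect_error(top_features(ranking, 10), "exceeds")
})

test_that("confusion counts match direct enumeration", {
  lab <- rep(c("seizure", "non-seizure"), each = 50)
  expect_equal(confusion(lab, lab), c(TP = 50, FP = 0, TN = 50, FN = 0))

  lab2 <- c(rep("seizure", 30), rep("non-seizure", 70))
  all_pos <- rep("seizure", 100)
  expect_equal(confusion(lab2, all_pos), c(TP = 30, FP = 70, TN = 0, FN = 0))

  for (seed in 1:5) {
    set.seed(seed)
    truth <- sample(c("seizure", "non-seizure"), 20, replace = TRUE)
    pred <- sample(c("seizure", "non-seizure"), 20, replace = TRUE)
    cc <- confusion(truth, pred)
    brute <- c(TP = 0, FP = 0, TN = 0, FN = 0)
    for (i in 1:20) {
      key <- if (truth[i] == "seizure" && pred[i] == "seizure") "TP"
        else if (truth[i] != "seizure" && pred[i] == "seizure") "FP"
        else if (truth[i] != "seizure" && pred[i] != "seizure") "TN"
        else "FN"
      brute[key] <- brute[key] + 1
    }
    expect_equal(cc, brute)
    expect_equal(sum(cc), 20)
  }

  expect_error(confusion(lab, rep("ictal", 100)), "unseen class")
  expect_error(confusion(lab, lab[1:10]), "equal length")
})

test_that("SEN/SPE/ACC formulas and their symmetries hold", {
  m <- sen_spe_acc(c(TP = 95, FN = 5, TN = 98, FP = 2))
  expect_equal(m, c(SEN = 95, SPE = 98, ACC = 96.5))

  expect_equal(sen_spe_acc(c(TP = 50, FP = 0, TN = 50, FN = 0)),
               c(SEN = 100, SPE = 100, ACC = 100))

  none_pos <- sen_spe_acc(c(TP = 0, FN = 0, TN = 10, FP = 2))
  expect_true(is.na(none_pos[["SEN"]]))

  # swapping TP<->TN and FP<->FN (positive-class relabeling) swaps SEN/SPE
  a <- sen_spe_acc(c(TP = 40, FP = 7, TN = 30, FN = 3))
  b <- sen_spe_acc(c(TP = 30, FP = 3, TN = 40, FN = 7))
  expect_equal(a[["SEN"]], b[["SPE"]])
  expect_equal(a[["SPE"]], b[["SEN"]])
  expect_equal(a[["ACC"]], b[["ACC"]])
})

test_that("cross-validation is stratified, deterministic, and leak-free by default", {
  tab <- separable_table(n_per_class = 40, seed = 2, exact = TRUE)
  cfg <- classifier_config(n_trees = 40, seed = 3)
  cv <- cross_validate(tab, cfg, k = 5, seed = 11)
  expect_equal(cv$summary$mean[cv$summary$metric == "ACC"], 100)
  expect_equal(cv$summary$sd[cv$summary$metric == "ACC"], 0)

  cv2 <- cross_validate(tab, cfg, k = 5, seed = 11)
  expect_equal(cv$folds, cv2$folds)

  g <- glance(cv)
  expect_equal(g$acc_mean, 100)
  expect_equal(nrow(tidy(cv)), 5)

  expect_error(cross_validate(tab, cfg, k = 50, seed = 1), "fewer members")
})

test_that("label-independent features score at chance accuracy", {
  accs <- numeric(6)
  for (r in seq_along(accs)) {
    tab <- separable_table(n_per_class = 30, gap = 0, seed = 100 + r)
    cv <- suppressWarnings(
      cross_validate(tab, classifier_config(n_trees = 30, seed = r), k = 5,
                     seed = r)
    )
    accs[r] <- cv$summary$mean[cv$summary$metric == "ACC"]
  }
  # binomial 3-sigma band around 50% for the pooled prediction count
  n_total <- 6 * 60
  band <- 3 * sqrt(0.25 / n_total) * 100
  expect_lt(abs(mean(accs) - 50), band + 5)
})

test_that("evaluation reports serialize to JSON and a readable table", {
  tab <- separable_table(n_per_class = 25, seed = 3)
  cv <- cross_validate(tab, classifier_config(n_trees = 30), k = 5, seed = 2)
  path <- tempfile(fileext = ".json")
  write_report(cv, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$k, 5)
  expect_equal(length(obj$folds), 5)
  txt <- readLines(sub("\\.json$", ".txt", path))
  expect_match(txt[1], "SEN")
  expect_match(txt[2], "100")
})
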