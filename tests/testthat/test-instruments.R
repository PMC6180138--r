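specs <- default_instruments()

test_that("shipped instrument specs match the published scoring rules", {
  expect_named(specs, c("DASS21", "EQ_SHORT", "JSE_S", "EES"))
  expect_equal(specs$DASS21$reversed_items, integer(0))
  expect_equal(specs$JSE_S$reversed_items, c(1L, 3L, 6L, 7L, 8L, 11L, 12L, 14L))
  expect_equal(specs$EES$reversed_items,
               c(2L, 3L, 4L, 7L, 9L, 10L, 11L, 12L, 15L, 16L, 17L))
  expect_equal(specs$EQ_SHORT$source_items,
               c(1L, 6L, 9L, 10L, 13L, 14L, 16L, 18L, 19L, 20L, 21L))
  for (s in specs) {
    expect_true(all(s$reversed_items >= 1 & s$reversed_items <= s$n_items))
    expect_true(s$scale_min <= s$binarize_cut && s$binarize_cut <= s$scale_max)
  }
})

test_that("binarization follows each instrument's dichotomization ranges", {
  # DASS-21: absence (0) vs presence (1-3)
  expect_equal(binarize_item(0:3, specs$DASS21, 11), c(0L, 1L, 1L, 1L))
  # EQ-short: no empathy (0-1) vs empathic (2-3)
  expect_equal(binarize_item(0:3, specs$EQ_SHORT, 7), c(0L, 0L, 1L, 1L))
  # JSE-S ordinary: empathic 4-7; reversed (e.g. item 6): empathic 1-3
  expect_equal(binarize_item(1:7, specs$JSE_S, 2), c(0L, 0L, 0L, 1L, 1L, 1L, 1L))
  expect_equal(binarize_item(1:7, specs$JSE_S, 6), c(1L, 1L, 1L, 0L, 0L, 0L, 0L))
  # EES ordinary (13): expressive 3-5; reversed (12): expressive 1-2
  expect_equal(binarize_item(3, specs$EES, 13), 1L)
  expect_equal(binarize_item(3, specs$EES, 12), 0L)
  expect_equal(binarize_item(NA, specs$EES, 1), NA_integer_)
})

test_that("reversed items code the exact complement of ordinary items", {
  for (s in specs[c("JSE_S", "EES")]) {
    rev_item <- s$reversed_items[1]
    ord_item <- setdiff(seq_len(s$n_items), s$reversed_items)[1]
    for (score in s$scale_min:s$scale_max)
      expect_equal(binarize_item(score, s, rev_item),
                   1L - binarize_item(score, s, ord_item))
  }
})

test_that("out-of-range scores are rejected naming instrument, item and value", {
  expect_error(binarize_item(9, specs$DASS21, 3), "DASS21.*item 3.*9")
  expect_error(binarize_item(0, specs$JSE_S, 1), "JSE_S")
  expect_error(binarize_item(1.5, specs$EES, 2), "EES")
})

test_that("binarize_table matches elementwise binarize_item and rejects bad columns", {
  set.seed(11)
  tab <- data.frame(
    participant_id = paste0("P", 1:6),
    time_point = rep(c("PRE", "POST"), each = 3),
    check.names = FALSE
  )
  cols <- list(`DASS-21: 11` = c("DASS21", 11), `DASS-21: 5` = c("DASS21", 5),
               `EES: 12` = c("EES", 12), `EES: 13` = c("EES", 13),
               `JSE-S: 6` = c("JSE_S", 6))
  for (cl in names(cols)) {
    s <- specs[[cols[[cl]][1]]]
    tab[[cl]] <- sample(s$scale_min:s$scale_max, 6, replace = TRUE)
  }
  bin <- binarize_table(tab, specs)
  for (cl in names(cols)) {
    s <- specs[[cols[[cl]][1]]]
    expect_equal(bin[[cl]],
                 binarize_item(tab[[cl]], s, as.integer(cols[[cl]][2])),
                 info = cl)
  }
  # all-minimum ordinary scores -> all zero
  low <- tab
  low$`DASS-21: 11` <- 0; low$`DASS-21: 5` <- 0; low$`EES: 13` <- 1
  lowbin <- binarize_table(low, specs)
  expect_true(all(lowbin$`DASS-21: 11` == 0) && all(lowbin$`EES: 13` == 0))
  # range violation and unknown columns error
  bad <- tab; bad$`DASS-21: 11`[2] <- 9
  expect_error(binarize_table(bad, specs), "DASS21")
  unk <- tab; names(unk)[3] <- "FOO: 1"
  expect_error(binarize_table(unk, specs), "FOO")
})

test_that("prevalence filter retains items iff both categories reach the threshold", {
  # N = 40, fraction 0.30: retained iff 12 <= presence count <= 28
  N <- 40
  mk <- function(count_pre, count_post) {
    tab <- data.frame(participant_id = rep(paste0("P", 1:N), 2),
                      time_point = rep(c("PRE", "POST"), each = N),
                      check.names = FALSE)
    tab[["DASS-21: 11"]] <- c(as.integer(1:N <= count_pre),
                              as.integer(1:N <= count_post))
    tab
  }
  expect_equal(filter_items(mk(22, 23)), "DASS-21: 11")
  expect_equal(filter_items(mk(40, 40)), character(0))  # one category empty
  expect_equal(filter_items(mk(11, 20)), character(0))  # fails at PRE
  expect_equal(filter_items(mk(12, 28)), "DASS-21: 11") # boundary in
  expect_equal(filter_items(mk(11, 29), per_time_point = FALSE),
               "DASS-21: 11")                            # pooled mode differs
  expect_error(filter_items(mk(20, 20)[0, ]), "empty")
})

test_that("prevalence filter equals a brute-force double count on random tables", {
  set.seed(21)
  for (rep in 1:5) {
    N <- 40
    m <- matrix(rbinom(N * 10, 1, runif(10, 0.1, 0.9)), N, 10, byrow = TRUE)
    colnames(m) <- paste0("EES: ", 1:10)
    kept <- filter_items(m, prevalence_fraction = 0.30)
    thr <- ceiling(0.30 * N)
    manual <- colnames(m)[colSums(m) >= thr & colSums(1 - m) >= thr]
    expect_equal(kept, manual)
  }
})

test_that("scale totals follow published scoring with reverse-scored items", {
  # single EES record with known scores: reversed items are recoded 6 - s
  tab <- data.frame(participant_id = "P1", time_point = "PRE",
                    check.names = FALSE)
  ees <- specs$EES
  scores <- rep(2L, ees$n_items)
  for (k in seq_len(ees$n_items)) tab[[paste0("EES: ", k)]] <- scores[k]
  tot <- scale_totals(tab, specs)
  manual <- sum(ifelse(seq_len(ees$n_items) %in% ees$reversed_items,
                       6L - scores, scores))
  expect_equal(tot$EES_total, manual)

  # DASS-21: raw sums; all-zero record -> 0; all-one record -> 21
  mk_dass <- function(v) {
    d <- data.frame(participant_id = "P1", time_point = "PRE",
                    check.names = FALSE)
    for (k in 1:21) d[[paste0("DASS-21: ", k)]] <- v
    d
  }
  z <- scale_totals(mk_dass(0L), specs)
  expect_equal(z$DASS21_total, 0)
  expect_equal(z$DASS21_depression + z$DASS21_anxiety + z$DASS21_stress, 0)
  o <- scale_totals(mk_dass(1L), specs)
  expect_equal(o$DASS21_total, 21)
  expect_equal(o$DASS21_stress, 7)

  # random DASS tables match an independent column-sum oracle
  set.seed(31)
  d <- data.frame(participant_id = paste0("P", 1:8), time_point = "PRE",
                  check.names = FALSE)
  for (k in 1:21) d[[paste0("DASS-21: ", k)]] <- sample(0:3, 8, replace = TRUE)
  got <- scale_totals(d, specs)
  expect_equal(got$DASS21_total, rowSums(as.matrix(d[, -(1:2)])))
})

test_that("paired t-test matches the textbook formula and flags degeneracy", {
  expect_equal(paired_t_test(c(1, 2, 3), c(1, 2, 3)),
               list(statistic = 0, df = 2L, p_value = 1,
                    mean_difference = 0, degenerate = TRUE))
  res <- paired_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_true(res$degenerate)
  expect_true(is.na(res$p_value))

  set.seed(41)
  pre <- rnorm(40, 10, 3); post <- pre + rnorm(40, 0.5, 1)
  res <- paired_t_test(pre, post)
  d <- post - pre
  t_manual <- mean(d) / (sd(d) / sqrt(40))
  p_manual <- 2 * pt(-abs(t_manual), 39)
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$df, 39)
  expect_equal(res$p_value, p_manual, tolerance = 1e-12)
  expect_false(res$degenerate)
})
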