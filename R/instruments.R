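#' Instrument metadata and binarization rules
#'
#' An `instrument_spec` bundles everything needed to score and binarize one
#' self-report instrument: the response range, the reverse-keyed items, the
#' binarization cut point, and (where defined) the subscale membership of
#' each item. Four instruments ship with the package (see
#' [default_instruments()]):
#'
#' * **DASS-21** (distress; 21 items, 0--3): item scores 1--3 code symptom
#'   *presence*, 0 codes absence (cut 1, no reversed items).
#' * **EQ-short** (empathy quotient, 11-item Korean short form; 0--3):
#'   2--3 code *empathic*, 0--1 no empathy (cut 2, no reversed items).
#' * **JSE-S** (Jefferson empathy, student version; 20 items, 1--7):
#'   4--7 code *empathic* for ordinary items; for the reverse-keyed items
#'   1, 3, 6, 7, 8, 11, 12, 14 the complementary rule applies (1--3 code
#'   empathic).
#' * **EES** (emotional expressivity; 17 items, 1--5): 3--5 code
#'   *expressive* for ordinary items; for the reverse-keyed items 2, 3, 4,
#'   7, 9, 10, 11, 12, 15, 16, 17 scores 1--2 code expressive.
#'
#' @param instrument_id One of `"DASS21"`, `"EQ_SHORT"`, `"JSE_S"`, `"EES"`,
#'   or any other identifier for a user-defined instrument.
#' @param label Display label used in column names, e.g. `"DASS-21"` so that
#'   item 11 is labelled `"DASS-21: 11"`.
#' @param n_items Number of items.
#' @param scale_min,scale_max Integer response range.
#' @param binarize_cut Integer cut `c`: an ordinary item codes 1 iff
#'   `score >= c`; a reverse-keyed item codes 1 iff `score < c`.
#' @param reversed_items Integer vector of 1-based reverse-keyed item numbers.
#' @param subscales Optional named list mapping subscale label to item
#'   numbers (e.g. DASS-21 depression/anxiety/stress).
#' @param source_items Optional integer vector recording, for a short form,
#'   which items of the parent instrument the positions 1..n_items map to.
#' @return An object of class `instrument_spec`.
#' @seealso [binarize_item()], [binarize_table()], [default_instruments()]
#' @export
instrument_spec <- function(instrument_id, label, n_items, scale_min, scale_max,
                            binarize_cut, reversed_items = integer(),
                            subscales = NULL, source_items = NULL) {
  n_items <- as.integer(n_items)
  reversed_items <- as.integer(reversed_items)
  stopifnot(
    length(instrument_id) == 1L, nzchar(instrument_id),
    n_items >= 1L,
    scale_min < scale_max,
    scale_min <= binarize_cut, binarize_cut <= scale_max,
    all(reversed_items >= 1L), all(reversed_items <= n_items),
    !anyDuplicated(reversed_items)
  )
  if (!is.null(subscales)) {
    items <- unlist(subscales, use.names = FALSE)
    stopifnot(all(items >= 1L), all(items <= n_items), !anyDuplicated(items))
  }
  if (!is.null(source_items)) stopifnot(length(source_items) == n_items)
  structure(
    list(instrument_id = instrument_id, label = label, n_items = n_items,
         scale_min = as.integer(scale_min), scale_max = as.integer(scale_max),
         binarize_cut = as.integer(binarize_cut),
         reversed_items = sort(reversed_items),
         subscales = subscales, source_items = source_items),
    class = "instrument_spec"
  )
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("<instrument_spec> %s (%s): %d items, range %d-%d, cut %d, %d reversed\n",
              x$instrument_id, x$label, x$n_items, x$scale_min, x$scale_max,
              x$binarize_cut, length(x$reversed_items)))
  invisible(x)
}

#' The four shipped instrument specifications
#'
#' Reads the instrument metadata file shipped under `extdata/instruments.yaml`
#' and returns validated [instrument_spec()] objects for the DASS-21,
#' EQ-short, JSE-S and EES.
#'
#' @param path Optional path to an alternative YAML file with the same layout.
#' @return Named list of `instrument_spec` objects keyed by instrument id.
#' @export
default_instruments <- function(path = NULL) {
  path <- path %||% system.file("extdata", "instruments.yaml", package = "empathnet")
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(id) {
    r <- raw[[id]]
    instrument_spec(
      instrument_id = id, label = r$label, n_items = r$n_items,
      scale_min = r$scale_min, scale_max = r$scale_max,
      binarize_cut = r$binarize_cut,
      reversed_items = unlist(r$reversed_items) %||% integer(),
      subscales = r$subscales, source_items = unlist(r$source_items)
    )
  })
  stats::setNames(out, names(raw))
}

#' Item labels for an instrument
#'
#' @param spec An [instrument_spec()].
#' @param items Item numbers (default all).
#' @return Character labels of the form `"<label>: <item>"`, the convention
#'   used for all column names in this package.
#' @export
item_labels <- function(spec, items = seq_len(spec$n_items)) {
  paste0(spec$label, ": ", items)
}

# Resolve "<label>: <item>" column labels against a list of specs.
# Returns data.frame(label, instrument_id, item).
parse_item_labels <- function(labels, specs) {
  by_label <- stats::setNames(
    names(specs), vapply(specs, `[[`, "", "label"))
  m <- regmatches(labels, regexec("^(.*): ([0-9]+)$", labels))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad))
    stop("column label(s) not of the form '<instrument>: <item>': ",
         paste(labels[bad], collapse = ", "))
  pre <- vapply(m, `[[`, "", 2L)
  item <- as.integer(vapply(m, `[[`, "", 3L))
  unknown <- !(pre %in% names(by_label))
  if (any(unknown))
    stop("no instrument spec matches column(s): ",
         paste(labels[unknown], collapse = ", "))
  id <- unname(by_label[pre])
  n_items <- vapply(specs, `[[`, 0L, "n_items")
  out_of_range <- item < 1L | item > n_items[id]
  if (any(out_of_range))
    stop("item number out of range for column(s): ",
         paste(labels[out_of_range], collapse = ", "))
  data.frame(label = labels, instrument_id = id, item = item,
             stringsAsFactors = FALSE)
}

#' Binarize a single item score
#'
#' Applies the instrument's dichotomization rule. For an ordinary item a
#' score of at least `binarize_cut` codes 1 (presence / empathic /
#' expressive). For a reverse-keyed item the complementary rule applies: a
#' score strictly below the cut codes 1 (so for the JSE-S, 1--7 with cut 4,
#' reversed items code 1 on scores 1--3; for the EES, 1--5 with cut 3,
#' reversed items code 1 on scores 1--2).
#'
#' @param score Integer score(s); `NA` is propagated.
#' @param spec An [instrument_spec()].
#' @param item_no 1-based item number (scalar).
#' @return Integer 0/1 vector of the same length as `score`.
#' @export
binarize_item <- function(score, spec, item_no) {
  stopifnot(inherits(spec, "instrument_spec"),
            length(item_no) == 1L, item_no >= 1L, item_no <= spec$n_items)
  ok <- is.na(score) | (score >= spec$scale_min & score <= spec$scale_max &
                          score == round(score))
  if (!all(ok))
    stop(sprintf("score out of range for %s item %d: %s (allowed %d-%d)",
                 spec$instrument_id, item_no,
                 paste(score[!ok], collapse = ", "),
                 spec$scale_min, spec$scale_max))
  if (item_no %in% spec$reversed_items)
    as.integer(score < spec$binarize_cut)
  else
    as.integer(score >= spec$binarize_cut)
}

# Split a response table into id columns and item score columns.
split_response_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  id_cols <- intersect(c("participant_id", "time_point"), names(tab))
  item_cols <- setdiff(names(tab), id_cols)
  if (length(item_cols) == 0L) stop("response table has no item columns")
  if ("time_point" %in% id_cols) {
    tp <- as.character(tab$time_point)
    if (!all(tp %in% c("PRE", "POST")))
      stop("time_point must be 'PRE' or 'POST'")
    if ("participant_id" %in% id_cols) {
      dup <- duplicated(paste(tab$participant_id, tp, sep = "\r"))
      if (any(dup))
        stop("participant appears more than once per time point: ",
             paste(unique(tab$participant_id[dup]), collapse = ", "))
    }
  }
  list(ids = tab[id_cols], items = tab[item_cols], id_cols = id_cols,
       item_cols = item_cols)
}

#' Binarize a Likert response table
#'
#' Applies [binarize_item()] column by column. The table may carry
#' `participant_id` and `time_point` columns, which are passed through
#' unchanged; every other column must be labelled `"<instrument>: <item>"`
#' (e.g. `"DASS-21: 11"`, `"EES: 3"`) and resolvable against `specs`.
#'
#' @param raw Data frame of raw ordinal scores.
#' @param specs Named list of [instrument_spec()] objects
#'   (default [default_instruments()]).
#' @return Data frame with the same rows and columns, item scores replaced
#'   by 0/1 codes.
#' @export
binarize_table <- function(raw, specs = default_instruments()) {
  parts <- split_response_table(raw)
  info <- parse_item_labels(parts$item_cols, specs)
  out <- raw
  for (k in seq_along(parts$item_cols)) {
    cl <- parts$item_cols[k]
    out[[cl]] <- binarize_item(raw[[cl]], specs[[info$instrument_id[k]]],
                               info$item[k])
  }
  out
}

#' Filter items by the dual-category prevalence criterion
#'
#' An item (network node) is retained only when *both* response categories
#' are sufficiently common: at least `ceiling(prevalence_fraction * N)`
#' participants with a 1 *and* at least as many with a 0, where `N` is the
#' number of participants per time point. With `per_time_point = TRUE` (the
#' default) the criterion must hold at every time point separately, so both
#' networks share one node set; with `FALSE` the records are pooled. With
#' the default fraction 0.30 and `N = 40` the threshold is 12 cases, i.e. an
#' item is retained iff its presence count lies in 12..28.
#'
#' @param binary Data frame of 0/1 codes as produced by [binarize_table()]
#'   (needs a `time_point` column for the per-time-point mode), or a plain
#'   0/1 matrix (treated as a single group).
#' @param prevalence_fraction Fraction of participants required in each
#'   category; default 0.30.
#' @param per_time_point Require the criterion at every time point (default
#'   `TRUE`).
#' @return Character vector of retained column labels, in input order.
#' @export
filter_items <- function(binary, prevalence_fraction = 0.30,
                         per_time_point = TRUE) {
  stopifnot(prevalence_fraction > 0, prevalence_fraction < 1)
  if (is.matrix(binary))
    binary <- as.data.frame(binary, check.names = FALSE)
  if (nrow(binary) == 0L) stop("empty response table")
  parts <- split_response_table(binary)
  m <- as.matrix(parts$items)
  if (!all(m %in% c(0L, 1L, NA)))
    stop("filter_items expects a binarized table (values 0/1)")
  groups <- if (per_time_point && "time_point" %in% parts$id_cols)
    split(seq_len(nrow(m)), as.character(binary$time_point))
  else
    list(all = seq_len(nrow(m)))
  keep <- rep(TRUE, ncol(m))
  for (rows in groups) {
    n <- length(rows)
    thr <- ceiling(prevalence_fraction * n)
    ones <- colSums(m[rows, , drop = FALSE] == 1L, na.rm = TRUE)
    zeros <- colSums(m[rows, , drop = FALSE] == 0L, na.rm = TRUE)
    keep <- keep & (ones >= thr) & (zeros >= thr)
  }
  parts$item_cols[keep]
}

#' Scale and subscale totals
#'
#' Sums raw item scores per record for each instrument present in the table,
#' using each instrument's published scoring: reverse-keyed items of the
#' JSE-S and EES are reverse-scored (`min + max - score`) before summing,
#' while the DASS-21 and EQ-short sum raw scores. DASS-21
#' depression/anxiety/stress subscale totals are reported alongside the
#' instrument total when the subscale items are present. Totals are only
#' computed for instruments whose full item set (or full subscale) appears
#' in the table; records with a missing value in a summed column get `NA`.
#'
#' @inheritParams binarize_table
#' @return Data frame with `participant_id`/`time_point` (when present) and
#'   one column per instrument/subscale total.
#' @export
scale_totals <- function(raw, specs = default_instruments()) {
  parts <- split_response_table(raw)
  info <- parse_item_labels(parts$item_cols, specs)
  out <- parts$ids

  scored <- function(id, items) {
    spec <- specs[[id]]
    cols <- parts$item_cols[info$instrument_id == id & info$item %in% items]
    nos <- info$item[match(cols, info$label)]
    vals <- vapply(seq_along(cols), function(k) {
      s <- raw[[cols[k]]]
      if (nos[k] %in% spec$reversed_items)
        s <- spec$scale_min + spec$scale_max - s
      as.numeric(s)
    }, numeric(nrow(raw)))
    if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L)
    rowSums(vals)
  }

  for (id in unique(info$instrument_id)) {
    spec <- specs[[id]]
    have <- sort(info$item[info$instrument_id == id])
    if (identical(have, seq_len(spec$n_items)))
      out[[paste0(id, "_total")]] <- scored(id, have)
    for (sub in names(spec$subscales)) {
      sub_items <- spec$subscales[[sub]]
      if (all(sub_items %in% have))
        out[[paste0(id, "_", sub)]] <- scored(id, sub_items)
    }
  }
  if (ncol(out) == length(parts$id_cols))
    warning("no complete instrument or subscale found; no totals computed")
  n_missing <- sum(!stats::complete.cases(out))
  if (n_missing > 0L)
    message(n_missing, " record(s) have missing totals due to missing item scores")
  out
}

#' Paired t-test for pre/post totals
#'
#' Standard paired t-test on `post - pre` differences with `n - 1` degrees
#' of freedom. When all differences are identical the statistic is
#' undefined (zero variance); this is reported via `degenerate = TRUE`
#' (with `t = 0, p = 1` in the all-zero case, `NA` otherwise).
#'
#' @param pre,post Numeric vectors of equal length, paired by participant.
#' @return List with `statistic`, `df`, `p_value`, `mean_difference`,
#'   `degenerate`.
#' @export
paired_t_test <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2L)
  d <- post - pre
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(statistic = 0, df = n - 1L, p_value = 1,
                  mean_difference = 0, degenerate = TRUE))
    return(list(statistic = NA_real_, df = n - 1L, p_value = NA_real_,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = unname(tt$estimate),
       degenerate = FALSE)
}

#' Published per-item presence counts for the default study scenario
#'
#' Per-item counts of participants coded 1 ("presence / empathic /
#' expressive"), at each of two time points, for the 24 items that pass the
#' 30% dual-category prevalence criterion in a 40-participant pre/post
#' empathy-training study of medical students. These counts define the
#' default calibration targets of the synthetic-data generator
#' (see [calibrate_marginals()]).
#'
#' @return Data frame with columns `label`, `instrument`, `item`,
#'   `subscale`, `presence_pre`, `presence_post`, `n_participants`.
#' @export
reference_presence_counts <- function() {
  read.csv(system.file("extdata", "reference_presence_counts.csv",
                       package = "empathnet"),
           check.names = FALSE, stringsAsFactors = FALSE)
}

#' Expand per-item presence counts into a binary response table
#'
#' Builds a deterministic 0/1 table whose per-item, per-time-point column
#' sums equal the given counts (the first `count` participants at each time
#' point code 1). Useful for exercising the prevalence filter against
#' published marginal counts when raw responses are unavailable.
#'
#' @param counts Data frame as returned by [reference_presence_counts()].
#' @return Data frame with `participant_id`, `time_point` and one 0/1
#'   column per item label.
#' @export
presence_counts_to_table <- function(counts = reference_presence_counts()) {
  N <- unique(counts$n_participants)
  stopifnot(length(N) == 1L)
  one_tp <- function(tp, col) {
    m <- vapply(seq_len(nrow(counts)), function(k)
      as.integer(seq_len(N) <= counts[[col]][k]), integer(N))
    colnames(m) <- counts$label
    cbind(data.frame(participant_id = paste0("P", seq_len(N)),
                     time_point = tp, stringsAsFactors = FALSE),
          as.data.frame(m, check.names = FALSE))
  }
  rbind(one_tp("PRE", "presence_pre"), one_tp("POST", "presence_post"))
}
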