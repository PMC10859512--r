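# Eligibility filtering, CESD-10 / GAD-7 scoring, prevalence and
# descriptive statistics.  All variances and standard deviations use the
# n - 1 divisor, consistently, including inside Cronbach's alpha.

is_item_missing <- function(v, codes = default_missing_codes()) {
  is.na(v) | as.character(v) %in% c(codes, "")
}

#' Apply the study eligibility filter
#'
#' Keeps rows with validated age at or above `min_age`, a diabetes
#' diagnosis flag set (when `require_dm`), and complete, valid responses on
#' all 17 items (any missing code excludes the row). Criteria are applied
#' sequentially in that order and per-criterion exclusion counts are
#' attached as the `"exclusions"` attribute.
#'
#' @param raw Survey table with `age`, `dm_diagnosed` and the 17 item
#'   columns.
#' @param min_age Minimum validated age in years (default 65).
#' @param require_dm Require the diabetes flag to be set (default TRUE).
#' @param items Item column names.
#' @param codes Missing-code tokens.
#' @return Data frame of eligible rows with integer item columns, original
#'   row order preserved; attribute `exclusions` holds the counts dropped
#'   by each criterion.
#' @export
filter_eligible <- function(raw, min_age = 65, require_dm = TRUE,
                            items = default_item_names(),
                            codes = default_missing_codes()) {
  need <- c("age", if (require_dm) "dm_diagnosed", items)
  absent <- setdiff(need, names(raw))
  if (length(absent))
    stop("required column(s) absent: ", paste(absent, collapse = ", "))

  n0 <- nrow(raw)
  keep_age <- !is.na(raw$age) & raw$age >= min_age
  step1 <- raw[keep_age, , drop = FALSE]
  n_age <- n0 - nrow(step1)

  if (require_dm) {
    keep_dm <- !is.na(step1$dm_diagnosed) & step1$dm_diagnosed %in%
      c(TRUE, 1, "1", "yes", "TRUE")
    step2 <- step1[keep_dm, , drop = FALSE]
  } else step2 <- step1
  n_dm <- nrow(step1) - nrow(step2)

  complete <- rep(TRUE, nrow(step2))
  for (col in items) {
    v <- step2[[col]]
    ok <- !is_item_missing(v, codes) &
      as.character(v) %in% c("0", "1", "2", "3")
    complete <- complete & ok
  }
  out <- step2[complete, , drop = FALSE]
  n_miss <- nrow(step2) - nrow(out)

  for (col in items) out[[col]] <- as.integer(as.character(out[[col]]))
  attr(out, "exclusions") <- c(age = n_age, dm = n_dm, incomplete = n_miss)
  out
}

#' Score the CESD-10 and GAD-7 scales
#'
#' Totals are plain sums: CESD-10 over items 1-10 (range 0-30) and GAD-7
#' over items 1-7 (range 0-21). Depression is flagged at CESD-10 >= 10;
#' anxiety severity bands use the 5 / 10 / 15 boundaries
#' (none < 5 <= mild < 10 <= moderate < 15 <= severe).
#'
#' @param table Eligible item-response table (integer items 0-3).
#' @param reverse_code Optional character vector of items to reverse-code
#'   (`3 - x`) for datasets where positive-affect items are not pre-coded;
#'   the default assumes all items are already coded so that higher means
#'   more severe.
#' @return Data frame with `cesd_total`, `gad_total`, `depressed`,
#'   `anxiety_band`.
#' @export
score_scales <- function(table, reverse_code = character(0)) {
  dep <- intersect(cesd_items(), names(table))
  anx <- intersect(gad_items(), names(table))
  stopifnot(length(dep) == 10, length(anx) == 7)
  items <- table[c(dep, anx)]
  vals <- as.matrix(items)
  if (any(is.na(vals)) || any(vals < 0 | vals > 3))
    stop("item responses must be complete and in {0, 1, 2, 3}")
  for (col in reverse_code) items[[col]] <- 3L - items[[col]]
  cesd <- as.integer(rowSums(items[dep]))
  gad <- as.integer(rowSums(items[anx]))
  band <- cut(gad, breaks = c(-Inf, 4, 9, 14, Inf),
              labels = c("none", "mild", "moderate", "severe"))
  data.frame(cesd_total = cesd, gad_total = gad,
             depressed = cesd >= 10L,
             anxiety_band = band)
}

#' Prevalence of depression, anxiety and their comorbidity
#'
#' Depression is CESD-10 total >= 10; anxiety presence is GAD-7 total >= 5
#' (the mild band or above); comorbidity requires both.
#'
#' @param records Score table from [score_scales()].
#' @return Named numeric vector of fractions `depression`, `anxiety`,
#'   `comorbid`.
#' @export
prevalence <- function(records) {
  if (nrow(records) == 0) stop("no score records: prevalence undefined")
  dep <- records$cesd_total >= 10
  anx <- records$gad_total >= 5
  c(depression = mean(dep), anxiety = mean(anx), comorbid = mean(dep & anx))
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total))`, with all
#' variances using the n - 1 divisor.
#'
#' @param items Data frame or matrix of k >= 2 item columns.
#' @return Alpha as a single number.
#' @export
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  k <- ncol(x)
  stopifnot(k >= 2, nrow(x) >= 2)
  vt <- var(rowSums(x))
  if (vt == 0) stop("total-score variance is zero: alpha undefined")
  (k / (k - 1)) * (1 - sum(apply(x, 2, var)) / vt)
}

#' Per-item descriptive statistics
#'
#' @param table Item-response table.
#' @param items Item column names.
#' @return Data frame with columns `item`, `mean`, `sd` (sample SD,
#'   n - 1 divisor).
#' @export
describe_items <- function(table, items = intersect(default_item_names(),
                                                    names(table))) {
  data.frame(item = items,
             mean = vapply(items, function(c) mean(table[[c]]), 0),
             sd = vapply(items, function(c) sd(table[[c]]), 0),
             row.names = NULL)
}
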