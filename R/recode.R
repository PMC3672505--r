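#' The seven injection risk behavior indicators
#'
#' Returns the canonical item set used throughout the package: relative
#' frequency of sharing syringes, cookers, cotton filters and rinse water,
#' frequency of using a new sterile syringe to divide drugs (a safe behavior,
#' reverse-coded), frequency of cleaning needles with bleach (reverse-coded),
#' and the number of people who shared a syringe with the respondent.
#' The first item (syringe sharing) and second (cooker sharing) also define
#' the canonical risk ordering of latent classes (see [lca_fit()]).
#'
#' @return A data.frame with columns `name`, `reversed` (logical; TRUE for
#'   safe behaviors whose scale must be flipped so higher = riskier) and
#'   `type` (`"likert"` for the six 7-point items, `"count"` for the partner
#'   count).
#' @export
lta_items <- function() {
  data.frame(
    name = c("share_syringe", "share_cooker", "share_cotton", "share_rinse",
             "new_syringe_divide", "bleach_clean", "n_sharing_partners"),
    reversed = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    type = c(rep("likert", 6), "count"),
    stringsAsFactors = FALSE
  )
}

#' Recode a 7-point Likert frequency item to the 3-category risk scale
#'
#' Raw items are measured on a 7-point scale labeled from "always" (1) to
#' "never" (7) with "about half the time" (4) as the midpoint. Safe behaviors
#' (using a new sterile syringe to divide drugs, cleaning with bleach) are
#' first reversed (`raw <- 8 - raw`) so that higher scores represent riskier
#' behavior for every item. The reversed-or-not value is then collapsed to
#' three categories: 7 -> 0 ("never"), 5-6 -> 1 ("less than half the time"),
#' 1-4 -> 2 ("half the time or more"; the midpoint belongs to the upper
#' category by its label).
#'
#' Missing values propagate: `NA` in gives `NA` out; recoding never imputes.
#'
#' @param raw Integer vector with values in 1..7, or `NA`.
#' @param reversed Logical scalar; `TRUE` for safe-behavior items.
#' @return Integer vector with values in `{0, 1, 2}` (`NA` preserved).
#' @export
#' @examples
#' recode_item(7)                 # never risky -> 0
#' recode_item(1, reversed = TRUE)  # "always" safe -> never risky -> 0
#' recode_item(4)                 # midpoint -> half the time or more -> 2
recode_item <- function(raw, reversed = FALSE) {
  stopifnot(is.logical(reversed), length(reversed) == 1L)
  r <- raw
  bad <- which(!is.na(r) & (r < 1 | r > 7 | r != round(r)))
  if (length(bad))
    stop(sprintf("likert value out of range 1..7 at position(s) %s (value %s)",
                 paste(utils::head(bad, 5), collapse = ", "), r[bad[1]]))
  r <- as.integer(round(r))
  if (reversed) r <- 8L - r
  out <- integer(length(r))
  out[!is.na(r) & r == 7L] <- 0L
  out[!is.na(r) & r >= 5L & r <= 6L] <- 1L
  out[!is.na(r) & r <= 4L] <- 2L
  out[is.na(r)] <- NA_integer_
  out
}

#' Recode the number of syringe-sharing partners to 3 categories
#'
#' Categories are none (0), one (1) and more than one (2).
#'
#' @param n Non-negative integer vector (`NA` allowed, preserved).
#' @return Integer vector in `{0, 1, 2}`.
#' @export
#' @examples
#' recode_partners(c(0, 1, 5))
recode_partners <- function(n) {
  bad <- which(!is.na(n) & (n < 0 | n != round(n)))
  if (length(bad))
    stop(sprintf("partner count must be a non-negative integer; bad value at position(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  out <- pmin(as.integer(round(n)), 2L)
  out[is.na(n)] <- NA_integer_
  out
}

.cohort_item_cols <- function() lta_items()$name

.cohort_required_cols <- function() {
  c("participant_id", "wave", "arm", .cohort_item_cols(),
    "sex", "age", "race", "site", "homeless", "randomized", "returned_6m")
}

#' Read a per-participant cohort file
#'
#' Reads a long-format CSV of raw assessments (one row per participant and
#' wave) and validates it: required columns present, Likert items in 1..7,
#' partner counts non-negative, ages in 15..30, waves in
#' `{baseline, m3, m6}`, arms in `{control, PEI, none}` (with `arm = "none"`
#' only for non-randomized participants), and no duplicated
#' `(participant_id, wave)` pair. Missing values are encoded as empty fields.
#' Unknown columns are preserved but ignored by downstream stages.
#'
#' @param path Path to a CSV file with a header row.
#' @return A data.frame of class `lta_cohort`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  validate_cohort(df)
}

#' Validate a raw cohort data.frame
#'
#' @param df A data.frame in the layout produced by [generate_cohort()] /
#'   read by [read_cohort()].
#' @return The validated data.frame, classed `lta_cohort`.
#' @export
validate_cohort <- function(df) {
  miss <- setdiff(.cohort_required_cols(), names(df))
  if (length(miss))
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "))
  if (!all(df$wave %in% c("baseline", "m3", "m6")))
    stop("wave must be one of baseline, m3, m6 (row ",
         which(!df$wave %in% c("baseline", "m3", "m6"))[1], ")")
  if (!all(df$arm %in% c("control", "PEI", "none")))
    stop("arm must be one of control, PEI, none (row ",
         which(!df$arm %in% c("control", "PEI", "none"))[1], ")")
  key <- paste(df$participant_id, df$wave)
  if (anyDuplicated(key))
    stop("duplicate (participant_id, wave) pair: ", key[anyDuplicated(key)])
  items <- lta_items()
  for (j in which(items$type == "likert")) {
    v <- df[[items$name[j]]]
    bad <- which(!is.na(v) & (v < 1 | v > 7 | v != round(v)))
    if (length(bad))
      stop(sprintf("item %s out of range 1..7 at row %d", items$name[j], bad[1]))
  }
  v <- df$n_sharing_partners
  bad <- which(!is.na(v) & (v < 0 | v != round(v)))
  if (length(bad))
    stop(sprintf("n_sharing_partners negative or non-integer at row %d", bad[1]))
  bad <- which(!is.na(df$age) & (df$age < 15 | df$age > 30))
  if (length(bad))
    stop(sprintf("age outside 15..30 at row %d", bad[1]))
  rand <- df$randomized %in% c(TRUE, "TRUE", 1)
  bad <- which(df$arm == "none" & rand)
  if (length(bad))
    stop(sprintf("arm 'none' for a randomized participant at row %d", bad[1]))
  class(df) <- c("lta_cohort", "data.frame")
  df
}

#' Recode a raw cohort into the 3-category indicator matrix
#'
#' Applies [recode_item()] (with the appropriate reversal for safe behaviors)
#' and [recode_partners()] to the seven risk items of every assessment row.
#' Rows stay aligned with the input; missing raw values stay missing.
#'
#' @param cohort An `lta_cohort` data.frame (see [read_cohort()]).
#' @return An object of class `indicator_matrix`: a list with `values`
#'   (N x 7 integer matrix in `{0,1,2}`/`NA`), `items` (item metadata),
#'   `participant_id`, `wave`, `arm`.
#' @export
recode_cohort <- function(cohort) {
  items <- lta_items()
  vals <- matrix(NA_integer_, nrow(cohort), nrow(items),
                 dimnames = list(NULL, items$name))
  for (j in seq_len(nrow(items))) {
    v <- cohort[[items$name[j]]]
    vals[, j] <- if (items$type[j] == "likert") {
      recode_item(v, reversed = items$reversed[j])
    } else {
      recode_partners(v)
    }
  }
  structure(list(values = vals, items = items,
                 participant_id = cohort$participant_id,
                 wave = cohort$wave, arm = cohort$arm),
            class = "indicator_matrix")
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat(sprintf("<indicator_matrix> %d assessments x %d items (%d missing entries)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Write / read an indicator matrix as CSV
#'
#' The CSV holds `participant_id`, `wave`, `arm` and the seven recoded items
#' coded 0/1/2 (0 = never / none, 1 = less than half the time / one,
#' 2 = half the time or more / more than one); missing values are empty
#' fields. `read_indicators(write_indicators(x, f))` reproduces `x` exactly,
#' and writing a file read by [read_indicators()] is byte-identical.
#'
#' @param x An `indicator_matrix`.
#' @param path Output CSV path.
#' @return `write_indicators()` returns `path` invisibly; `read_indicators()`
#'   returns an `indicator_matrix`.
#' @export
write_indicators <- function(x, path) {
  stopifnot(inherits(x, "indicator_matrix"))
  df <- data.frame(participant_id = x$participant_id, wave = x$wave,
                   arm = x$arm, x$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_indicators
#' @export
read_indicators <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  items <- lta_items()
  miss <- setdiff(c("participant_id", "wave", "arm", items$name), names(df))
  if (length(miss))
    stop("indicator file missing column(s): ", paste(miss, collapse = ", "))
  vals <- as.matrix(df[items$name])
  storage.mode(vals) <- "integer"
  if (any(!is.na(vals) & !(vals %in% 0:2)))
    stop("indicator entries must be 0, 1 or 2")
  structure(list(values = vals, items = items,
                 participant_id = df$participant_id,
                 wave = df$wave, arm = df$arm),
            class = "indicator_matrix")
}
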