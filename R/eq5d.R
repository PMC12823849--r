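#' @name eq5d
#' @title EQ-5D-5L profiles, state space, and value sets
#'
#' @description
#' The EQ-5D-5L instrument scores five dimensions — mobility, self-care,
#' usual activities, pain/discomfort, anxiety/depression — on five levels
#' each ("no problems" = 1 to "extreme problems" = 5), giving 5^5 = 3,125
#' health states. A state code such as "11111" (full health) is mapped to a
#' utility index through a country-specific value set anchored at 1 for
#' full health and 0 for dead; values below 0 (worse than dead) are legal.
NULL

eq5d_dims <- c("mo", "sc", "ua", "pd", "ad")

#' Encode an EQ-5D-5L profile as a 5-character state code
#'
#' @param levels Integer vector of length 5 (mobility, self-care, usual
#'   activities, pain/discomfort, anxiety/depression), each in 1..5.
#' @return The concatenated digit string, e.g. "12345".
#' @export
profile_code <- function(levels) {
  if (length(levels) != 5L || any(is.na(levels)))
    stopf("an EQ-5D-5L profile has exactly five levels")
  if (any(levels != as.integer(levels)) || any(levels < 1L) || any(levels > 5L))
    stopf("EQ-5D-5L levels must be integers in 1..5")
  paste(as.integer(levels), collapse = "")
}

#' Enumerate all 3,125 EQ-5D-5L state codes
#'
#' @return Character vector of the 5^5 codes in lexicographic order,
#'   from "11111" to "55555".
#' @export
enumerate_states <- function() {
  g <- expand.grid(ad = 1:5, pd = 1:5, ua = 1:5, sc = 1:5, mo = 1:5)
  paste0(g$mo, g$sc, g$ua, g$pd, g$ad)
}

#' Construct an EQ-5D-5L value set
#'
#' @param values Named numeric vector: names are the 3,125 state codes,
#'   values the utility indices (all <= 1, "11111" exactly 1).
#' @param name Label for the tariff.
#' @return An object of class `eq5d_value_set`.
#' @export
eq5d_value_set <- function(values, name = "custom") {
  codes <- enumerate_states()
  if (is.null(names(values)) || !setequal(names(values), codes))
    stopf("a value set must define all 3,125 state codes exactly once")
  values <- values[codes]
  if (any(values > 1 + 1e-12)) stopf("value-set indices must not exceed 1")
  if (abs(values[["11111"]] - 1) > 1e-12) stopf('value set must anchor "11111" at 1')
  structure(list(name = name, values = values), class = "eq5d_value_set")
}

#' Synthetic additive-decrement value set
#'
#' A stand-in tariff for tests and default runs: the index is 1 minus a sum
#' of per-dimension decrements that grow with the level, so it is anchored
#' at 1 for "11111", monotone non-increasing in every dimension, and
#' reaches a worse-than-dead minimum for "55555" — the qualitative shape of
#' published Chinese EQ-5D-5L tariffs, but not their coefficients (which
#' are external data and must be supplied via [read_value_set()] for a
#' real-tariff analysis).
#'
#' @return An `eq5d_value_set`.
#' @export
synthetic_value_set <- function() {
  # per-dimension level-5 decrements; intermediate levels scale by `steps`
  max_dec <- c(mo = 0.346, sc = 0.305, ua = 0.195, pd = 0.281, ad = 0.264)
  steps <- c(0, 0.25, 0.50, 0.80, 1)
  g <- expand.grid(ad = 1:5, pd = 1:5, ua = 1:5, sc = 1:5, mo = 1:5)
  dec <- max_dec["mo"] * steps[g$mo] + max_dec["sc"] * steps[g$sc] +
    max_dec["ua"] * steps[g$ua] + max_dec["pd"] * steps[g$pd] +
    max_dec["ad"] * steps[g$ad]
  values <- stats::setNames(1 - dec, paste0(g$mo, g$sc, g$ua, g$pd, g$ad))
  eq5d_value_set(values, name = "synthetic-additive")
}

#' Read / write a value set as CSV (columns `code`, `value`)
#'
#' @param path CSV file with 3,125 rows.
#' @param name Tariff label for the loaded set.
#' @return [read_value_set()] returns an `eq5d_value_set`;
#'   [write_value_set()] its path, invisibly.
#' @export
read_value_set <- function(path, name = basename(path)) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  if (!all(c("code", "value") %in% names(df)))
    stopf("value-set CSV needs columns `code` and `value`")
  eq5d_value_set(stats::setNames(df$value, df$code), name = name)
}

#' @rdname read_value_set
#' @param vs An `eq5d_value_set`.
#' @export
write_value_set <- function(vs, path) {
  stopifnot(inherits(vs, "eq5d_value_set"))
  utils::write.csv(data.frame(code = names(vs$values), value = unname(vs$values)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Utility index of a state code under a value set
#'
#' @param code 5-character state code ("11111".."55555").
#' @param value_set An `eq5d_value_set`.
#' @return The utility index (<= 1).
#' @export
index_value <- function(code, value_set) {
  stopifnot(inherits(value_set, "eq5d_value_set"))
  if (!is.character(code) || length(code) != 1L || !grepl("^[1-5]{5}$", code))
    stopf("malformed EQ-5D-5L code: %s", deparse(code))
  v <- value_set$values[[code]]
  if (is.null(v)) stopf("code %s absent from value set", code)
  v
}

#' Mean utility of a patient stratum
#'
#' Indexes every patient's EQ-5D-5L profile and returns the stratum mean
#' with a normal-approximation 95% CI, shaped as a utility parameter for
#' the model assembly step.
#'
#' @param records Patient data frame with integer columns `mo`, `sc`,
#'   `ua`, `pd`, `ad`.
#' @param value_set An `eq5d_value_set`.
#' @param state Health-state label the estimate feeds (default "Survival").
#' @return A one-row data frame: `state`, `mean`, `ci_low`, `ci_high`.
#' @export
mean_utility <- function(records, value_set, state = "Survival") {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stopf("empty stratum: no records to summarize")
  if (!all(eq5d_dims %in% names(records)))
    stopf("records must carry EQ-5D-5L columns %s", paste(eq5d_dims, collapse = ", "))
  codes <- apply(as.matrix(records[eq5d_dims]), 1L, function(x) profile_code(x))
  idx <- vapply(codes, index_value, numeric(1), value_set = value_set)
  m <- mean(idx)
  se <- if (length(idx) > 1L) stats::sd(idx) / sqrt(length(idx)) else 0
  half <- stats::qnorm(0.975) * se
  data.frame(state = state, mean = m,
             ci_low = m - half, ci_high = min(m + half, 1))
}
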