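#' YFAS-C item-to-symptom mapping
#'
#' The 25-item Yale Food Addiction Scale for Children maps its scored items
#' onto seven DSM-IV-style dependence symptoms plus a clinical
#' impairment/distress criterion:
#'
#' * substance taken in larger amounts / longer than intended: items 1, 2, 3
#' * persistent desire or unsuccessful attempts to cut down: items 4, 17, 18, 25
#' * much time spent obtaining, using, recovering: items 5, 6, 7
#' * important activities given up or reduced: items 8, 9, 10, 11
#' * use continued despite adverse consequences: item 21
#' * tolerance: items 22, 23
#' * withdrawal / substance taken to relieve it: items 12, 13, 14
#' * impairment/distress: items 15, 16
#'
#' Items 19, 20 and 24 are administered but never scored.
#'
#' @return list with elements `symptoms` (named list of item vectors),
#'   `impairment` (item vector) and `unscored` (item vector).
#' @export
yfasc_symptom_map <- function() {
  list(
    symptoms = list(
      larger_amount_longer   = c(1L, 2L, 3L),
      persistent_desire      = c(4L, 17L, 18L, 25L),
      time_spent             = c(5L, 6L, 7L),
      activities_given_up    = c(8L, 9L, 10L, 11L),
      continued_despite_harm = 21L,
      tolerance              = c(22L, 23L),
      withdrawal             = c(12L, 13L, 14L)
    ),
    impairment = c(15L, 16L),
    unscored = c(19L, 20L, 24L)
  )
}

#' Default endorsement rule for raw YFAS-C responses
#'
#' An endorsement map turns each raw item response into endorsed / not
#' endorsed. Likert items (scored 0 "never" .. 4 "always") are endorsed at or
#' above a per-item cut point; dichotomous items are endorsed on "yes". The
#' published instrument description does not print the per-item cut points
#' nor which five items are dichotomous, so both are configuration; this
#' default treats the impairment items and the three unscored items as
#' dichotomous and endorses Likert items at >= 3 ("often"). All scoring
#' results downstream of endorsement are invariant to this choice.
#'
#' @param likert_cut integer in 1..4; minimum Likert response counted as
#'   endorsed (applied to every Likert item).
#' @param dichotomous_items integer vector of the five yes/no items.
#' @return object of class `endorsement_map`.
#' @export
default_endorsement_map <- function(likert_cut = 3L,
                                    dichotomous_items = c(15L, 16L, 19L, 20L, 24L)) {
  stopifnot(likert_cut >= 1L, likert_cut <= 4L,
            all(dichotomous_items %in% 1:25))
  structure(list(likert_cut = as.integer(likert_cut),
                 dichotomous_items = as.integer(dichotomous_items)),
            class = "endorsement_map")
}

## Convert one subject's raw responses (named or positional, length 25) into
## a logical endorsement vector. Likert responses are integers 0..4;
## dichotomous responses may be "yes"/"no", TRUE/FALSE or 1/0.
endorse_items <- function(responses, map) {
  if (length(responses) != 25L)
    stop("expected exactly 25 item responses, got ", length(responses))
  out <- logical(25L)
  for (i in 1:25) {
    r <- responses[[i]]
    if (is.na(r)) { out[i] <- NA; next }
    if (i %in% map$dichotomous_items) {
      out[i] <- if (is.character(r)) tolower(r) == "yes" else as.logical(r)
    } else {
      v <- suppressWarnings(as.numeric(r))
      if (is.na(v) || v < 0 || v > 4)
        stop("item ", i, ": Likert response must lie in 0..4")
      out[i] <- v >= map$likert_cut
    }
  }
  out
}

#' Score YFAS-C responses into the seven-symptom profile
#'
#' A symptom is counted as present when at least one of its mapped items is
#' endorsed; the impairment/distress criterion is met when item 15 or item 16
#' is endorsed (any-endorsed rule). Items 19, 20 and 24 are ignored.
#'
#' @param responses either a logical vector of length 25 (already-endorsed
#'   indicators) or a raw response vector of length 25 (Likert integers 0..4
#'   and yes/no for dichotomous items).
#' @param endorsement an `endorsement_map` used when `responses` is raw.
#' @param zero_fill if `TRUE`, a missing scored item is treated as not
#'   endorsed (the binary zero-fill policy) and the profile is flagged via
#'   attribute `zero_filled`; if `FALSE` (default) missing scored items are an
#'   error.
#' @return object of class `symptom_profile`: list with `symptoms` (named
#'   logical of length 7), `impairment` (logical) and `symptom_count`
#'   (integer 0..7).
#' @examples
#' e <- rep(FALSE, 25); e[c(1, 4, 5, 15)] <- TRUE
#' score_symptoms(e)$symptom_count  # 3
#' @export
score_symptoms <- function(responses, endorsement = default_endorsement_map(),
                           zero_fill = FALSE) {
  endorsed <- if (is.logical(responses) && length(responses) == 25L) {
    responses
  } else {
    endorse_items(responses, endorsement)
  }
  map <- yfasc_symptom_map()
  scored <- sort(c(unlist(map$symptoms), map$impairment))
  if (anyNA(endorsed[scored])) {
    if (!zero_fill)
      stop("missing scored item(s): ",
           paste(scored[is.na(endorsed[scored])], collapse = ", "),
           " (set zero_fill = TRUE to treat as not endorsed)")
    filled <- TRUE
    endorsed[is.na(endorsed)] <- FALSE
  } else filled <- FALSE
  symptoms <- vapply(map$symptoms, function(items) any(endorsed[items]),
                     logical(1))
  profile <- structure(
    list(symptoms = symptoms,
         impairment = any(endorsed[map$impairment]),
         symptom_count = sum(symptoms)),
    class = "symptom_profile")
  attr(profile, "zero_filled") <- filled
  profile
}

#' @export
print.symptom_profile <- function(x, ...) {
  cat("<symptom_profile> count =", x$symptom_count,
      "| impairment =", x$impairment, "\n")
  invisible(x)
}

#' Food-addiction diagnosis from a symptom profile
#'
#' FA is present when at least three of the seven symptoms are met *and* the
#' clinical impairment/distress criterion holds.
#'
#' @param profile a `symptom_profile` from [score_symptoms()].
#' @return logical: `TRUE` for a positive FA diagnosis.
#' @export
diagnose <- function(profile) {
  stopifnot(inherits(profile, "symptom_profile"))
  profile$symptom_count >= 3L && isTRUE(profile$impairment)
}

#' Score a wide table of YFAS-C responses
#'
#' @param items data.frame with one row per child and columns
#'   `item_1` .. `item_25`.
#' @inheritParams score_symptoms
#' @return data.frame with the seven symptom indicators, `impairment`,
#'   `symptom_count` and `food_addiction`.
#' @export
score_yfasc <- function(items, endorsement = default_endorsement_map(),
                        zero_fill = FALSE) {
  cols <- paste0("item_", 1:25)
  if (!all(cols %in% names(items)))
    stop("missing item columns: ",
         paste(setdiff(cols, names(items)), collapse = ", "))
  rows <- lapply(seq_len(nrow(items)), function(i) {
    p <- score_symptoms(unlist(items[i, cols], use.names = FALSE),
                        endorsement, zero_fill)
    c(as.list(p$symptoms),
      list(impairment = p$impairment, symptom_count = p$symptom_count,
           food_addiction = diagnose(p)))
  })
  do.call(rbind, lapply(rows, as.data.frame))
}
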