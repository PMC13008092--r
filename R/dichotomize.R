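#' Dichotomize a raw indicator column
#'
#' Converts a continuous or ordinal survey item to the 0/1 coding the
#' network analysis expects, under one of three rules:
#'
#' * `median_split` — values strictly below the sample median are coded 1
#'   (the "low"/event class); values at or above the median are coded 0.
#'   The median is the lower sample median (type-1 quantile), so ties at
#'   the median always fall in the non-event class. Used for, e.g., grip
#'   strength split into low vs high.
#' * `cutpoint` — values on the `event_side` of `cut` are coded 1.
#' * `recode_map` — explicit mapping from observed response levels to
#'   0/1, as for Likert loneliness items where "often" and "some of the
#'   time" code high loneliness on negatively worded items.
#'
#' @param raw Numeric or character/factor vector.
#' @param rule One of `"median_split"`, `"cutpoint"`, `"recode_map"`.
#' @param cut Numeric cutpoint (rule `"cutpoint"`).
#' @param event_side `"below"` (default: raw < cut is the event) or
#'   `"above"` (raw >= cut is the event).
#' @param map Named numeric vector of 0/1 values keyed by response level
#'   (rule `"recode_map"`).
#' @return Integer vector in {0, 1}.
#' @examples
#' dichotomize(c(20, 29, 35, 40), "median_split")  # 1 0 0 0: low grip
#' dichotomize(c("often", "hardly ever"), "recode_map",
#'             map = c(often = 1, "some of the time" = 1, "hardly ever" = 0))
#' @export
dichotomize <- function(raw, rule = c("median_split", "cutpoint",
                                      "recode_map"),
                        cut = NULL, event_side = c("below", "above"),
                        map = NULL) {
  rule <- match.arg(rule)
  if (anyNA(raw)) stop("dichotomize: missing values in input", call. = FALSE)
  if (rule == "median_split") {
    raw <- as.numeric(raw)
    if (length(unique(raw)) < 2)
      stop("dichotomize: median_split needs >= 2 distinct values",
           call. = FALSE)
    m <- stats::quantile(raw, 0.5, type = 1, names = FALSE)
    return(as.integer(raw < m))
  }
  if (rule == "cutpoint") {
    if (is.null(cut)) stop("dichotomize: cutpoint rule needs `cut`",
                           call. = FALSE)
    raw <- as.numeric(raw)
    event_side <- match.arg(event_side)
    return(if (event_side == "below") as.integer(raw < cut)
           else as.integer(raw >= cut))
  }
  # recode_map
  if (is.null(map) || is.null(names(map)))
    stop("dichotomize: recode_map rule needs a named `map`", call. = FALSE)
  if (!all(map %in% c(0, 1)))
    stop("dichotomize: map values must be 0/1", call. = FALSE)
  key <- as.character(raw)
  unmapped <- setdiff(unique(key), names(map))
  if (length(unmapped) > 0)
    stop("dichotomize: unmapped levels: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  as.integer(map[key])
}
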