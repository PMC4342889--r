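# Preprocessing recipes for the two worked examples, both classic
# Hosmer-Lemeshow teaching datasets: the low birth weight study (189
# mothers; `MASS::birthwt` ships the raw table) and the mammography
# experience survey (412 women).

#' Prepare the low birth weight dataset for an ordinal fit
#'
#' Builds the 4-category ordinal dataset from the raw low-birth-weight table:
#' birth weight in grams becomes the response, cut at 3500/3000/2500 g with
#' category 1 the heaviest (`> 3500`) and 4 the lightest (`<= 2500`), so a
#' covariate that lowers birth weight gets a negative cumulative-logit slope.
#' Three-category `RACE` becomes the indicators `OTHERvsWHITE` and
#' `BLACKvsWHITE`; the counts `PTL` (premature labors) and `FTV` (physician
#' visits) are dichotomized at greater-than-zero; `AGE`, `SMOKE`, `HT`, `UI`
#' pass through.
#'
#' Column names are matched case-insensitively, so `MASS::birthwt` works
#' directly.
#'
#' @param raw Data frame with columns `AGE`, `RACE` (1 = white, 2 = black,
#'   3 = other), `SMOKE`, `PTL`, `HT`, `UI`, `FTV`, `BWT`.
#' @return A [grid_dataset()] with covariates in the order `AGE`,
#'   `OTHERvsWHITE`, `BLACKvsWHITE`, `SMOKE`, `PTL`, `HT`, `UI`, `FTV`.
#' @examples
#' lbw <- prepare_lbw(MASS::birthwt)
#' lbw
#' @export
prepare_lbw <- function(raw) {
  names(raw) <- toupper(names(raw))
  need <- c("AGE", "RACE", "SMOKE", "PTL", "HT", "UI", "FTV", "BWT")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("prepare_lbw: missing column(s): ", paste(miss, collapse = ", "))
  }
  bwt <- raw$BWT
  y <- ifelse(bwt > 3500, 1L, ifelse(bwt > 3000, 2L, ifelse(bwt > 2500, 3L, 4L)))
  X <- cbind(
    AGE = as.numeric(raw$AGE),
    OTHERvsWHITE = as.numeric(raw$RACE == 3),
    BLACKvsWHITE = as.numeric(raw$RACE == 2),
    SMOKE = as.numeric(raw$SMOKE),
    PTL = as.numeric(raw$PTL > 0),
    HT = as.numeric(raw$HT),
    UI = as.numeric(raw$UI),
    FTV = as.numeric(raw$FTV > 0)
  )
  grid_dataset(y, X, K = 4L)
}

#' Prepare the mammography experience dataset for a multinomial fit
#'
#' The response `ME` is mammography experience (1 = over a year ago,
#' 2 = within a year, 3 = never; 3 is the reference class). The 4-category
#' attitude item `SYMPT` ("no mammogram needed unless symptoms appear",
#' 1 = strongly agree .. 4 = strongly disagree) becomes three indicators and
#' the 3-category perceived-detectability item `DETC` becomes two, each
#' against a reference level; `PB` (perceived benefit), `HIST` (family
#' history) and `BSE` (taught breast self-examination) pass through.
#'
#' The source tables do not document which levels anchored the published
#' indicator coding, so the reference levels are arguments; the defaults use
#' the lowest level of each item.
#'
#' @param raw Data frame with columns `ME`, `SYMPT` (1-4), `PB`, `HIST`,
#'   `BSE`, `DETC` (1-3). Names are matched case-insensitively.
#' @param sympt_ref Reference level for `SYMPT` (default 1).
#' @param detc_ref Reference level for `DETC` (default 1).
#' @return A [grid_dataset()] with covariates `SYMPT1..3`, `PB`, `HIST`,
#'   `BSE`, `DETC1..2`.
#' @export
prepare_mam <- function(raw, sympt_ref = 1L, detc_ref = 1L) {
  names(raw) <- toupper(names(raw))
  need <- c("ME", "SYMPT", "PB", "HIST", "BSE", "DETC")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("prepare_mam: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(raw$SYMPT %in% 1:4)) stop("prepare_mam: SYMPT must be coded 1..4")
  if (!all(raw$DETC %in% 1:3)) stop("prepare_mam: DETC must be coded 1..3")
  sympt_lev <- setdiff(1:4, sympt_ref)
  detc_lev <- setdiff(1:3, detc_ref)
  X <- cbind(
    SYMPT1 = as.numeric(raw$SYMPT == sympt_lev[1L]),
    SYMPT2 = as.numeric(raw$SYMPT == sympt_lev[2L]),
    SYMPT3 = as.numeric(raw$SYMPT == sympt_lev[3L]),
    PB = as.numeric(raw$PB),
    HIST = as.numeric(raw$HIST),
    BSE = as.numeric(raw$BSE),
    DETC1 = as.numeric(raw$DETC == detc_lev[1L]),
    DETC2 = as.numeric(raw$DETC == detc_lev[2L])
  )
  grid_dataset(as.integer(raw$ME), X, K = 3L)
}
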