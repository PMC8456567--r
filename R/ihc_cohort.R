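#' Published male LUSC immunohistochemistry cohort: baseline tables
#'
#' Clinicopathological counts of a published cohort of 102 male lung
#' squamous carcinoma patients after R0 resection, stratified by ER-alpha
#' immunohistochemistry status (23 positive, 79 negative). Each element is a
#' contingency table (rows = characteristic levels, columns = ER+ / ER-)
#' suitable for [chi_squared_association()]; the lymph-node (pN) row of the
#' original table is not reconstructable from the source and is omitted.
#'
#' @return list with elements `age` (>=65 / <65), `pT` (T1-T4), `stage`
#'   (I-III), `grade` (GI+II / GIII), `adjctx` (yes/no), `adjrad` (yes/no),
#'   plus `n_total` and `n_er_positive`.
#' @export
lusc_ihc_tables <- function() {
  tab <- function(m, rn) matrix(m, ncol = 2, byrow = TRUE,
                                dimnames = list(rn, c("ER_pos", "ER_neg")))
  list(
    age = tab(c(9, 19, 14, 60), c("ge65", "lt65")),
    pT = tab(c(8, 28, 8, 30, 4, 13, 3, 8), paste0("T", 1:4)),
    stage = tab(c(8, 27, 8, 28, 7, 24), c("I", "II", "III")),
    grade = tab(c(14, 51, 9, 28), c("G1_2", "G3")),
    adjctx = tab(c(15, 52, 8, 27), c("yes", "no")),
    adjrad = tab(c(7, 24, 16, 55), c("yes", "no")),
    n_total = 102L,
    n_er_positive = 23L
  )
}

#' Baseline association screen of the published cohort
#'
#' Runs [chi_squared_association()] over every characteristic of
#' [lusc_ihc_tables()] and reports the ER positivity rate.
#'
#' @return list with `tests` (data.frame: characteristic, chi2, df, p) and
#'   `er_positive_pct` (percentage, 2 decimals).
#' @export
lusc_ihc_association <- function() {
  tabs <- lusc_ihc_tables()
  chars <- c("age", "pT", "stage", "grade", "adjctx", "adjrad")
  res <- do.call(rbind, lapply(chars, function(ch) {
    ct <- chi_squared_association(tabs[[ch]])
    data.frame(characteristic = ch, chi2 = ct$chi2, df = ct$df, p = ct$p,
               stringsAsFactors = FALSE)
  }))
  list(tests = res,
       er_positive_pct = round(100 * tabs$n_er_positive / tabs$n_total, 2))
}
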