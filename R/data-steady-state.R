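#' Published steady-state parameters of the cyclase and its loop1 variants
#'
#' The printed steady-state table for the wild-type enzyme, ten loop1 point
#' variants and the fluorophore-labelled wild type, at 25 C: turnover number
#' `kcat` (1/s), Michaelis constant `KM` (uM) for the substrate, and the
#' printed specificity constant `kcat/KM` (1/(M s)) with its propagated SE.
#' Four inactive variants carry only an upper limit on `kcat` (no detectable
#' turnover with 0.1 uM enzyme and 40 uM substrate) and have `NA` in the
#' remaining columns.
#'
#' The specificity-constant columns are the values as printed (2 significant
#' digits); [propagate_kcat_over_km()] recomputes them from the `kcat` and
#' `KM` columns.
#'
#' @return A tibble with columns `variant`, `kcat`, `kcat_se`, `kcat_limit`,
#'   `KM`, `KM_se`, `spec_printed`, `spec_se_printed`.
#' @examples
#' tb <- steady_state_table()
#' with(tb[1, ], propagate_kcat_over_km(kcat, kcat_se, KM, KM_se))
#' @export
steady_state_table <- function() {
  tibble::tribble(
    ~variant, ~kcat, ~kcat_se, ~kcat_limit, ~KM, ~KM_se, ~spec_printed, ~spec_se_printed,
    "wt", 2.4, 0.2, NA, 4.5, 0.5, 5.3e5, 0.7e5,
    "K19A", 1.1, 0.1, NA, 6.1, 1.8, 1.8e5, 0.6e5,
    "G20A", 2.2e-2, 0.1e-2, NA, 2.1, 0.2, 1.0e4, 0.1e4,
    "G20P", NA, NA, 2.0e-3, NA, NA, NA, NA,
    "T21G", 1.8e-2, 0.1e-2, NA, 5.0, 0.8, 3.6e3, 0.6e3,
    "T21P", NA, NA, 2.0e-3, NA, NA, NA, NA,
    "N22A", 2.9e-1, 0.2e-1, NA, 8.4, 1.7, 3.4e4, 0.7e4,
    "F23A", 5.5e-3, 0.4e-3, NA, 6.8, 1.3, 8.1e2, 1.6e2,
    "E24P", NA, NA, 2.0e-3, NA, NA, NA, NA,
    "L26A", 1.1, 0.03, NA, 2.0, 0.3, 5.5e5, 0.8e5,
    "D28A", 2.4, 0.1, NA, 4.5, 0.9, 5.3e5, 1.1e5,
    "G30A", 1.0e-1, 0.1e-1, NA, 3.7, 1.3, 2.7e4, 1.0e4,
    "G30P", NA, NA, 2.0e-3, NA, NA, NA, NA,
    "F38A", 2.3, 0.1, NA, 3.5, 0.6, 6.6e5, 1.2e5,
    "wt CouA", 1.5, 0.1, NA, 4.1, 0.9, 3.7e5, 0.8e5)
}
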