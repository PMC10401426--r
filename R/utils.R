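stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_count <- function(x) is_scalar_num(x) && x >= 0 && x == floor(x)

#' Round half away from zero
#'
#' Commercial spreadsheet/statistics packages round 0.5 up, whereas base R
#' rounds half to even. Cohort summary percentages follow the half-up
#' convention (e.g. 76.15 prints as 76.2 at one decimal).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  # guard against representation error just below .5 (e.g. 76.15 * 10)
  floor(abs(x) * scale + 0.5 + 1e-9) / scale * sign(x)
}

## Marker panel used throughout: logical flag columns on the cell table.
#' Phenotype marker panel
#'
#' The flag columns recognised on a cell table: CD3 and CD8 T-cell markers,
#' NKp46 and CD56 NK-cell markers, and MHC class I. `phenotype` (a primary
#' label per cell) is carried alongside when present but the spatial layer
#' operates on flags.
#'
#' @return character vector of marker/flag names.
#' @export
cell_panel <- function() c("CD3", "CD8", "NKp46", "CD56", "MHC1")
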