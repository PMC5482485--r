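#' Packaged study Q-matrices
#'
#' Extended Q-matrices of the two packaged simulation studies over K = 5
#' attributes.  Study 1 uses ten three-attribute items with four substantive
#' options plus a NOA option (controlled OCMP); dropping the NOA option
#' (`controlled = FALSE`) gives the uncontrolled variant.  Study 2 mixes
#' five two-attribute four-option OCOP items with five three-attribute
#' five-option controlled-OCMP items.  `J = 20` doubles the ten-item form.
#'
#' @param study 1 or 2.
#' @param J Test length, 10 or 20.
#' @param controlled For study 1: keep (`TRUE`) or drop (`FALSE`) the NOA
#'   option.
#' @return A `gndm_qmatrix`.
#' @examples
#' sim_qmatrix(1, J = 10)
#' @export
sim_qmatrix <- function(study = 1, J = 10, controlled = TRUE) {
  stopifnot(study %in% c(1, 2), J %in% c(10, 20))
  file <- system.file(
    "extdata",
    sprintf("sim%d_extended_qmatrix.csv", study),
    package = "gndm", mustWork = TRUE
  )
  x <- readr::read_csv(file, show_col_types = FALSE)
  if (study == 1 && !controlled) {
    x <- filter(x, .data$option != 5)
  }
  if (J == 20) {
    x2 <- mutate(x, item = .data$item + 10L)
    x <- bind_rows(x, x2)
  }
  extended_qmatrix(x)
}

#' Packaged generating item-quality parameters
#'
#' The expected-pattern selection probability `e` and unexpected-pattern
#' probability `u` used to generate responses in the packaged studies.  In
#' study 1 every item has five options under the controlled design
#' (`e = 0.600, u = 0.100` at low quality; `e = 0.760, u = 0.060` at high)
#' and four options under the uncontrolled design (`e = 0.625, u = 0.125`;
#' `e = 0.775, u = 0.075`), keeping `e - u` equal across designs.  In
#' study 2 the three-attribute items keep the controlled study-1 values
#' while the two-attribute four-option items use the same `e` with
#' `u = (1 - e) / 3` (0.1333 at low, 0.0800 at high quality) so each
#' generating row is a probability vector.
#'
#' @param study 1 or 2.
#' @param quality `"low"` or `"high"`.
#' @param controlled For study 1: controlled or uncontrolled design.
#' @return A tibble with columns `item_group`, `e`, `u`.
#' @export
sim_quality <- function(study = 1, quality = c("low", "high"),
                        controlled = TRUE) {
  quality <- match.arg(quality)
  stopifnot(study %in% c(1, 2))
  if (study == 1) {
    e <- if (controlled) c(low = 0.600, high = 0.760)[[quality]]
    else c(low = 0.625, high = 0.775)[[quality]]
    u <- if (controlled) c(low = 0.100, high = 0.060)[[quality]]
    else c(low = 0.125, high = 0.075)[[quality]]
    tibble(item_group = "all", e = e, u = u)
  } else {
    e <- c(low = 0.600, high = 0.760)[[quality]]
    u <- c((1 - e) / 3, (1 - e) / 4)
    tibble(
      item_group = c("two-attribute", "three-attribute"),
      e = e,
      u = u
    )
  }
}
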