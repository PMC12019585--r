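#' Reference guild mass inventory
#'
#' Loads the published reference inventory of annual mean nitrogen masses
#' (mmol N m^-2, whole-domain per unit area) shipped with the package: the
#' Northeast Greenland shelf model states for the 2010s and 2050s and the
#' Barents Sea 2010s state used as a sense check. Values are packaged
#' verbatim and are immutable; they serve as inputs for the headline change
#' statistics and as a realistic initial condition.
#'
#' @return Data frame with columns `compartment` (display label),
#'   `GL_2010s`, `GL_2050s`, `BS_2010s`; exactly 35 rows.
#' @export
#' @examples
#' inv <- load_mass_fixture()
#' inv[inv$compartment == "Maritime mammals", "GL_2010s"]
load_mass_fixture <- function() {
  path <- system.file("extdata", "guild_mass_reference.csv",
                      package = "shelfweb", mustWork = TRUE)
  x <- utils::read.csv(path, check.names = FALSE)
  if (nrow(x) != 35 || !identical(names(x), c("compartment", "GL_2010s",
                                              "GL_2050s", "BS_2010s"))) {
    stop("packaged mass inventory is corrupted")
  }
  if (any(x[, -1] <= 0)) stop("packaged mass inventory has non-positive masses")
  lbl <- sort(unname(report_label()))
  if (!identical(sort(x$compartment), lbl)) {
    stop("packaged mass inventory labels do not match the compartment inventory")
  }
  x
}

#' Build a model state from the reference inventory
#'
#' Maps a column of the reference inventory onto the internal state vector.
#' The combined labile-plus-refractory sediment row is split: the labile pool
#' receives the combined value minus the refractory row.
#'
#' @param column one of `"GL_2010s"`, `"GL_2050s"`, `"BS_2010s"`.
#' @return Named state vector over [compartment_names()].
#' @export
reference_state <- function(column = "GL_2010s") {
  x <- load_mass_fixture()
  vals <- stats::setNames(x[[column]], x$compartment)
  cn <- compartment_names()
  st <- stats::setNames(numeric(length(cn)), cn)
  lab <- report_label(cn)
  for (i in seq_along(cn)) st[[i]] <- vals[[lab[[i]]]]
  st[["sediment_labile"]] <- vals[["Sediment labile plus refractory detritus"]] -
    vals[["Sediment refractory detritus"]]
  st
}
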