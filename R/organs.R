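#' Organ kinds of the simulated wheat plant
#'
#' The plant is resolved into six functional compartments: roots, a senescent
#' leaf cohort, mature and growing leaves (the photosynthetic sources), an
#' emerging leaf, and the grain. Mature and growing leaves assimilate carbon;
#' roots take up nitrate; the senescent cohort only remobilizes its labile
#' stores back to the common pool.
#'
#' @return Character vector of the six organ kinds, in canonical order.
#' @export
organ_kinds <- function() {
  c("roots", "senescent_leaf", "mature_leaf", "growing_leaf",
    "emerging_leaf", "grain")
}

#' @rdname organ_kinds
#' @export
photosynthetic_kinds <- function() c("mature_leaf", "growing_leaf")

#' @rdname organ_kinds
#' @export
leaf_kinds <- function() {
  c("senescent_leaf", "mature_leaf", "growing_leaf", "emerging_leaf")
}

# source organs subject to stress-driven downregulation
source_kinds <- function() c("mature_leaf", "growing_leaf", "roots")

new_organ_state <- function(kind, structural_mass, c_store, n_store,
                            defense_pool = 0, defense_n = 0,
                            s0 = 0, d_coef = 0) {
  structure(list(
    kind = kind,
    structural_mass = structural_mass,
    c_store = c_store,
    n_store = n_store,
    defense_pool = defense_pool,  # g defense compound accumulated
    defense_n = defense_n,        # g N immobilized in defense compounds
    s0 = s0,
    d_coef = d_coef,
    maintenance_deficit = FALSE,  # flag: unmet maintenance this day
    deficit_cum = 0               # cumulative unmet maintenance, g C
  ), class = "organ_state")
}

organ_area <- function(organ, sla) {
  if (organ$kind %in% leaf_kinds()) organ$structural_mass * sla[[organ$kind]] else 0
}

#' @export
print.organ_state <- function(x, ...) {
  cat(sprintf(
    "<organ_state> %s: mass %.4g g, C store %.4g g, N store %.4g g, s0 %.3f, D %.3f\n",
    x$kind, x$structural_mass, x$c_store, x$n_store, x$s0, x$d_coef))
  invisible(x)
}
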