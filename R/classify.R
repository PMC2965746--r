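#' Classify the ecological outcome of a simulation
#'
#' Summarizes the end state of a trajectory over a final evaluation window
#' (by default the last 20% of the run, to be robust to the persistent
#' predator-prey oscillations of these systems):
#'
#' * **persisting** populations: mean density over the window above
#'   `persistence_floor` (phage must additionally have no `phage_extinct`
#'   event and a final density above the extinction threshold);
#' * **dominant** population: the bacterial population with the highest mean
#'   density over the window (free phage, counted in particles rather than
#'   cells, are reported separately via `phage_persisted`);
#' * **regime**: `"washout"` if no bacterial population persists; otherwise
#'   `"phage-limited"` when the mean resource concentration over the window
#'   exceeds `limitation_fraction * A` (resources abundant, so predation is
#'   what limits the cells), else `"resource-limited"`.
#'
#' @param traj A `crispr_trajectory`.
#' @param window_frac Fraction of the run forming the final evaluation
#'   window (default 0.2). The trajectory must span at least twice the
#'   window.
#' @param persistence_floor Density (per ml) above which a population counts
#'   as persisting (default 1).
#' @param limitation_fraction Fraction of the reservoir concentration `A`
#'   above which the community counts as phage-limited (default 0.5).
#'
#' @return An object of class `outcome_summary` with fields `dominant`,
#'   `persisting`, `phage_persisted`, `regime`, `final_mean` (named mean
#'   densities over the window), `final_R`, and `window` (start/end times).
#' @export
classify_outcome <- function(traj, window_frac = 0.2, persistence_floor = 1,
                             limitation_fraction = 0.5) {
  stopifnot(inherits(traj, "crispr_trajectory"))
  if (window_frac <= 0 || window_frac > 0.5)
    stop("'window_frac' must be in (0, 0.5]")
  t_end <- max(traj$time)
  w_start <- (1 - window_frac) * t_end
  in_win <- traj$time >= w_start
  if (sum(in_win) < 2 || t_end <= 0)
    stop("trajectory too short: it must span at least twice the evaluation window")

  win <- traj$state[in_win, , drop = FALSE]
  means <- colMeans(win)
  pops <- setdiff(colnames(traj$state), "R")
  has_phage <- "P" %in% pops
  bact <- setdiff(pops, "P")

  persisting <- pops[means[pops] > persistence_floor]
  phage_persisted <- NA
  if (has_phage) {
    extinct <- any(traj$events$event == "phage_extinct")
    final_P <- traj$state[nrow(traj$state), "P"]
    phage_persisted <- !extinct && final_P > traj$env$phage_extinction_threshold
    if (!phage_persisted) persisting <- setdiff(persisting, "P")
  }

  bact_persisting <- intersect(bact, persisting)
  if (length(bact_persisting) == 0) {
    dominant <- NA_character_
    regime <- "washout"
  } else {
    dominant <- bact[which.max(means[bact])]
    regime <- if (means[["R"]] > limitation_fraction * traj$env$A)
      "phage-limited" else "resource-limited"
  }

  structure(
    list(dominant = dominant, persisting = persisting,
         phage_persisted = phage_persisted, regime = regime,
         final_mean = means[pops], final_R = means[["R"]],
         window = c(start = w_start, end = t_end),
         settings = list(window_frac = window_frac,
                         persistence_floor = persistence_floor,
                         limitation_fraction = limitation_fraction)),
    class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat("Ecological outcome\n")
  cat(sprintf("  regime: %s\n", x$regime))
  cat(sprintf("  dominant population: %s\n",
              if (is.na(x$dominant)) "(none)" else x$dominant))
  cat(sprintf("  persisting: %s\n",
              if (length(x$persisting)) paste(x$persisting, collapse = ", ")
              else "(none)"))
  if (!is.na(x$phage_persisted))
    cat(sprintf("  phage persisted: %s\n", x$phage_persisted))
  cat(sprintf("  mean densities over final window [%g, %g] hr:\n",
              x$window[["start"]], x$window[["end"]]))
  for (nm in names(x$final_mean))
    cat(sprintf("    %-4s %.4g per ml\n", nm, x$final_mean[[nm]]))
  cat(sprintf("    R    %.4g ug/ml\n", x$final_R))
  invisible(x)
}

outcome_to_list <- function(x) {
  list(dominant = if (is.na(x$dominant)) NULL else x$dominant,
       persisting = as.list(x$persisting),
       phage_persisted = if (is.na(x$phage_persisted)) NULL else x$phage_persisted,
       regime = x$regime,
       final_mean = as.list(x$final_mean),
       final_R = x$final_R,
       window = as.list(x$window))
}
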