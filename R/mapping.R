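#' Interpolate a calcein dose-response surface for one agent
#'
#' Replicate responses are averaged at each measured (intensity,
#' concentration) point, then interpolated by separable natural cubic
#' splines: first along intensity (linear scale), then along log10
#' concentration (the measured concentrations span more than a decade).
#' The interpolant passes through the replicate means exactly (no
#' smoothing) and is clipped to \[0, 100\] %.  Queries outside the measured
#' ranges are rejected rather than extrapolated.
#'
#' @param table a response table: data.frame with columns `agent`,
#'   `i_spta_mw_cm2`, `conc_ppml`, `pct_positive` (and optionally `rep`).
#' @param agent which agent's rows to use; defaults to the only agent
#'   present.
#' @param intensity_grid,conc_grid query grids (mW/cm^2, particles/mL);
#'   must lie within the measured ranges.
#' @return An object of class `response_surface`: list with
#'   `intensity` (grid), `concentration` (grid), `values` (matrix,
#'   intensity x concentration, %), `agent`.
#' @export
interpolate_surface <- function(table, agent = NULL, intensity_grid,
                                conc_grid) {
  stopifnot(all(c("i_spta_mw_cm2", "conc_ppml", "pct_positive") %in%
                  names(table)))
  if (!is.null(agent)) {
    table <- table[table$agent == agent, , drop = FALSE]
  } else if ("agent" %in% names(table)) {
    agent <- unique(table$agent)
    if (length(agent) != 1L) stop("table holds several agents; pick one")
  } else {
    agent <- ""
  }
  if (nrow(table) == 0L) stop("no rows for the requested agent")
  ints <- sort(unique(table$i_spta_mw_cm2))
  concs <- sort(unique(table$conc_ppml))
  if (length(ints) < 2L || length(concs) < 2L) {
    stop("need at least 2 intensity levels and 2 concentrations")
  }
  below <- function(x, lo) x < lo - 1e-9 * max(abs(lo), 1)
  above <- function(x, hi) x > hi + 1e-9 * max(abs(hi), 1)
  if (below(min(intensity_grid), min(ints)) ||
      above(max(intensity_grid), max(ints)) ||
      below(min(conc_grid), min(concs)) ||
      above(max(conc_grid), max(concs))) {
    stop("query grid extends outside the measured ranges (no extrapolation)")
  }
  # replicate means at the measured knots
  knot <- matrix(NA_real_, length(ints), length(concs))
  for (i in seq_along(ints)) {
    for (j in seq_along(concs)) {
      sel <- table$i_spta_mw_cm2 == ints[i] & table$conc_ppml == concs[j]
      if (!any(sel)) stop("response table is not a full factorial design")
      knot[i, j] <- mean(table$pct_positive[sel])
    }
  }
  spl <- function(x, y, xout) {
    if (length(x) < 4L) {
      spline(x, y, xout = xout, method = "natural")$y
    } else {
      splinefun(x, y, method = "natural")(xout)
    }
  }
  # separable pass: intensity first, then log10 concentration
  half <- vapply(seq_along(concs),
                 function(j) spl(ints, knot[, j], intensity_grid),
                 numeric(length(intensity_grid)))
  half <- matrix(half, nrow = length(intensity_grid))
  vals <- t(vapply(seq_along(intensity_grid),
                   function(i) spl(log10(concs), half[i, ], log10(conc_grid)),
                   numeric(length(conc_grid))))
  vals <- matrix(pmin(100, pmax(0, vals)), nrow = length(intensity_grid))
  structure(
    list(intensity = intensity_grid, concentration = conc_grid,
         values = vals, agent = agent),
    class = "response_surface"
  )
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf(
    "<response_surface> %s: %d x %d grid, response %.3g-%.3g%%\n",
    x$agent, length(x$intensity), length(x$concentration),
    min(x$values), max(x$values)))
  invisible(x)
}

#' Best-agent map over an (intensity, concentration) grid
#'
#' For each grid cell, picks the agent with the largest interpolated
#' response and records the winning margin (best minus second best, in
#' percentage points).  Exact ties are listed jointly (names joined by
#' `"|"`) with zero margin rather than broken by agent order.
#'
#' @param surfaces a named list of `response_surface` objects on identical
#'   grids (names are the agent labels), or a response table holding
#'   several agents together with `intensity_grid`/`conc_grid` to build
#'   them.
#' @param intensity_grid,conc_grid grids used when `surfaces` is a table.
#' @return An object of class `best_agent_map`: list with `intensity`,
#'   `concentration`, `winner` (character matrix), `margin` (numeric
#'   matrix, percentage points), `agents`.
#' @export
best_agent_map <- function(surfaces, intensity_grid = NULL,
                           conc_grid = NULL) {
  if (is.data.frame(surfaces)) {
    stopifnot(!is.null(intensity_grid), !is.null(conc_grid))
    agents <- unique(surfaces$agent)
    surfaces <- lapply(setNames(agents, agents), function(ag) {
      interpolate_surface(surfaces, ag, intensity_grid, conc_grid)
    })
  }
  stopifnot(is.list(surfaces), length(surfaces) >= 1L,
            !is.null(names(surfaces)))
  ref <- surfaces[[1L]]
  for (s in surfaces) {
    stopifnot(inherits(s, "response_surface"))
    if (!isTRUE(all.equal(s$intensity, ref$intensity)) ||
        !isTRUE(all.equal(s$concentration, ref$concentration))) {
      stop("surfaces are not on identical grids")
    }
  }
  agents <- names(surfaces)
  ni <- length(ref$intensity)
  nc <- length(ref$concentration)
  winner <- matrix("", ni, nc)
  margin <- matrix(0, ni, nc)
  for (i in seq_len(ni)) {
    for (j in seq_len(nc)) {
      v <- vapply(surfaces, function(s) s$values[i, j], 0)
      top <- max(v)
      tied <- agents[v == top]
      winner[i, j] <- paste(tied, collapse = "|")
      margin[i, j] <- if (length(v) > 1L) top - max(v[v < top], -Inf) else 0
      if (!is.finite(margin[i, j])) margin[i, j] <- 0
    }
  }
  structure(
    list(intensity = ref$intensity, concentration = ref$concentration,
         winner = winner, margin = margin, agents = agents),
    class = "best_agent_map"
  )
}

#' @export
print.best_agent_map <- function(x, ...) {
  tab <- sort(table(x$winner), decreasing = TRUE)
  cat(sprintf("<best_agent_map> %d x %d cells: %s\n",
              nrow(x$winner), ncol(x$winner),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Read a calcein response table from delimited text
#'
#' Expects a header `agent,i_spta_mw_cm2,conc_ppml,pct_positive,rep`.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_response_table <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("agent", "i_spta_mw_cm2", "conc_ppml", "pct_positive")
                %in% names(df)))
  df
}
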