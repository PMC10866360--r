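#' @title Hierarchical multi-objective ranking
#' @description
#' A hierarchy-based scalarization for lead-candidate selection: objectives
#' are ordered by importance, each with an absolute tolerance. At each
#' level, points meeting the tolerance form the feasible block and are
#' ordered by the next level; infeasible points follow, ordered by their
#' value at this level. Maximize goals are normalized by negating both
#' values and tolerances. Only the induced ordering is used for selection,
#' not a stitched merit function.
#' @name moo-chimera
NULL

#' One ranking objective
#'
#' @param name objective name (unique within a spec); either a property
#'   column or a derived objective computed by `transform`
#' @param goal "minimize" or "maximize"
#' @param tolerance absolute threshold defining the feasible block
#' @param transform optional function(data.frame) -> numeric for derived
#'   objectives (e.g. |vee - 3.2|); default: the column `name`
#' @return a `chimera_objective`
#' @export
chimera_objective <- function(name, goal = c("minimize", "maximize"),
                              tolerance, transform = NULL) {
  goal <- match.arg(goal)
  stopifnot(is.finite(tolerance))
  structure(list(name = name, goal = goal, tolerance = tolerance,
                 absolute = TRUE, transform = transform),
            class = "chimera_objective")
}

#' Ranking specification
#'
#' @param ... `chimera_objective`s in decreasing importance
#' @return a `ranking_spec`
#' @export
ranking_spec <- function(...) {
  objectives <- list(...)
  stopifnot(length(objectives) >= 1)
  nms <- vapply(objectives, function(o) o$name, character(1))
  if (anyDuplicated(nms)) stop("objective names must be unique")
  structure(list(objectives = objectives), class = "ranking_spec")
}

#' Lead-validation ranking presets
#'
#' Objective A: bi-objective, STG (minimize, tolerance 5.00) then OS
#' (maximize, tolerance 0.35). Objective B: tri-objective, STG (minimize,
#' 3.000), OS (maximize, 0.175), then the absolute VEE difference to 3.2 eV
#' (minimize, 0.350). All tolerances absolute.
#'
#' @param which "A" or "B"
#' @return a [ranking_spec()]
#' @export
lead_ranking_spec <- function(which = c("A", "B")) {
  which <- match.arg(which)
  if (which == "A") {
    ranking_spec(
      chimera_objective("stg", "minimize", 5.00),
      chimera_objective("os", "maximize", 0.35)
    )
  } else {
    ranking_spec(
      chimera_objective("stg", "minimize", 3.000),
      chimera_objective("os", "maximize", 0.175),
      chimera_objective("vee_diff", "minimize", 0.350,
                        transform = function(d) abs(d$vee - 3.2))
    )
  }
}

# objective values normalized to minimization, as a matrix, plus tolerances
chimera_values <- function(points, spec) {
  vals <- vapply(spec$objectives, function(o) {
    v <- if (is.null(o$transform)) {
      if (!o$name %in% names(points)) stop("missing objective value: ", o$name)
      points[[o$name]]
    } else {
      o$transform(points)
    }
    if (anyNA(v)) stop("missing objective value in '", o$name, "'")
    if (o$goal == "maximize") -v else v
  }, numeric(nrow(points)))
  tol <- vapply(spec$objectives, function(o)
    if (o$goal == "maximize") -o$tolerance else o$tolerance, numeric(1))
  list(values = matrix(vals, nrow = nrow(points)), tol = tol)
}

#' Hierarchical ordering
#'
#' @param points data.frame of property values; a `canonical` column, when
#'   present, breaks ties deterministically
#' @param spec a [ranking_spec()]
#' @return integer permutation of row indices, best first
#' @export
chimera_order <- function(points, spec) {
  cv <- chimera_values(points, spec)
  v <- cv$values; tol <- cv$tol
  tie <- if ("canonical" %in% names(points)) points$canonical
         else sprintf("%09d", seq_len(nrow(points)))
  nlev <- ncol(v)
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  rec <- function(idx, level) {
    if (length(idx) <= 1L) return(idx)
    feas <- idx[v[idx, level] <= tol[level]]
    infeas <- setdiff(idx, feas)
    infeas <- infeas[order(v[infeas, level], tie[infeas])]
    head <- if (level == nlev) {
      feas[order(v[feas, level], tie[feas])]
    } else {
      rec(feas, level + 1L)
    }
    c(head, infeas)
  }
  rec(seq_len(nrow(points)), 1L)
}

#' Select the top n of a ranking
#'
#' @param points data.frame of property values
#' @param spec a [ranking_spec()]
#' @param n how many (>= 1); capped at the number of points
#' @return the selected rows, best first
#' @export
select_top <- function(points, spec, n) {
  stopifnot(n >= 1)
  ord <- chimera_order(points, spec)
  points[ord[seq_len(min(n, length(ord)))], , drop = FALSE]
}

#' Merge two rankings
#'
#' Union by canonical form, stable order: all of `a` first, then the rows
#' of `b` not already present.
#'
#' @param a,b data.frames with a `canonical` column
#' @return merged data.frame; attribute "n_overlap" gives the intersection
#'   size
#' @export
merge_rankings <- function(a, b) {
  keep <- !(b$canonical %in% a$canonical)
  out <- rbind(a, b[keep, , drop = FALSE])
  attr(out, "n_overlap") <- sum(!keep)
  out
}
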