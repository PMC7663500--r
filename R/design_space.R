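#' Design-space construction
#'
#' A design space is an ordered set of system functionalities (e.g. spotting
#' algorithm, data sampling strategy, microcontroller, runtime mode), each
#' realised by one of several candidate components, each component tunable
#' through finite parameter grids. A configuration picks exactly one
#' component per functionality and binds every parameter of the chosen
#' components to one grid value.
#'
#' @param id symbolic identifier, unique within its parent.
#' @param name human-readable name (defaults to `id`).
#' @param components list of [component_spec()]s (at least one).
#' @param params named list of finite, non-empty parameter value vectors.
#' @return `functionality` / `component_spec` objects.
#' @seealso [design_space()], [enumerate_configurations()]
#' @export
functionality <- function(id, components, name = id) {
  stopifnot(is.character(id), length(id) == 1)
  if (length(components) == 0)
    stop("functionality '", id, "' needs at least one component")
  stopifnot(all(vapply(components, inherits, logical(1), "component_spec")))
  cids <- vapply(components, `[[`, character(1), "id")
  if (anyDuplicated(cids))
    stop("duplicate component ids in functionality '", id, "'")
  names(components) <- cids
  structure(list(id = id, name = name, components = components),
            class = "functionality")
}

#' @rdname functionality
#' @export
component_spec <- function(id, params = list(), name = id) {
  stopifnot(is.character(id), length(id) == 1, is.list(params))
  if (length(params)) {
    if (is.null(names(params)) || any(!nzchar(names(params))))
      stop("parameter domains must be named")
    bad <- vapply(params, function(v) length(v) == 0, logical(1))
    if (any(bad))
      stop("empty parameter domain in component '", id, "'")
  }
  structure(list(id = id, name = name, params = params),
            class = "component_spec")
}

#' Assemble a validated design space
#'
#' @param functionalities list of [functionality()] objects (at least one,
#'   unique ids). Declaration order defines the enumeration order.
#' @return A `design_space` object.
#' @examples
#' sp <- design_space(list(
#'   functionality("algorithm", list(
#'     component_spec("fft", params = list(m = c(1, 5, 13))),
#'     component_spec("wpd", params = list(m = c(0.5, 1), d = c(15, 20))))),
#'   functionality("mcu", list(
#'     component_spec("arm_cortexm3"), component_spec("msp430f1611")))))
#' n_configurations(sp)
#' @export
design_space <- function(functionalities) {
  if (length(functionalities) == 0)
    stop("a design space needs at least one functionality")
  stopifnot(all(vapply(functionalities, inherits, logical(1),
                       "functionality")))
  ids <- vapply(functionalities, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate functionality ids")
  names(functionalities) <- ids
  structure(list(functionalities = functionalities), class = "design_space")
}

#' @export
print.design_space <- function(x, ...) {
  cat("<design_space> ", length(x$functionalities), " functionalities, ",
      n_configurations(x), " configurations\n", sep = "")
  for (fn in x$functionalities) {
    cat("  ", fn$id, ": ", sep = "")
    cat(paste(vapply(fn$components, function(cp) {
      if (length(cp$params))
        paste0(cp$id, "(", paste(names(cp$params), collapse = ","), ")")
      else cp$id
    }, character(1)), collapse = " | "), "\n")
  }
  invisible(x)
}

#' Closed-form configuration count
#'
#' Product over functionalities of the sum over components of the product
#' of their parameter-domain sizes.
#'
#' @param space a [design_space()].
#' @return Integer count.
#' @export
n_configurations <- function(space) {
  stopifnot(inherits(space, "design_space"))
  prod(vapply(space$functionalities, function(fn) {
    sum(vapply(fn$components, function(cp) {
      if (length(cp$params)) prod(lengths(cp$params)) else 1
    }, numeric(1)))
  }, numeric(1)))
}

#' Enumerate every configuration of a design space
#'
#' Deterministic lexicographic order: functionalities in declaration order,
#' within a functionality components in declaration order, within a
#' component parameter grids in declaration order with the last parameter
#' varying fastest. Earlier functionalities vary slowest.
#'
#' @param space a [design_space()].
#' @return List of `configuration` objects. Each configuration is a named
#'   list (by functionality id) of `list(component = id, params = named
#'   list)`.
#' @export
enumerate_configurations <- function(space) {
  stopifnot(inherits(space, "design_space"))
  per_fn <- lapply(space$functionalities, function(fn) {
    out <- list()
    for (cp in fn$components) {
      if (length(cp$params)) {
        grid <- expand.grid(rev(cp$params), KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
        grid <- grid[, rev(seq_along(cp$params)), drop = FALSE]
        names(grid) <- names(cp$params)
        for (i in seq_len(nrow(grid)))
          out[[length(out) + 1]] <- list(component = cp$id,
                                         params = as.list(grid[i, , drop = FALSE]))
      } else {
        out[[length(out) + 1]] <- list(component = cp$id, params = list())
      }
    }
    out
  })
  idx <- lapply(per_fn, seq_along)
  combos <- expand.grid(rev(idx), KEEP.OUT.ATTRS = FALSE)
  combos <- combos[, rev(seq_along(idx)), drop = FALSE]
  lapply(seq_len(nrow(combos)), function(i) {
    cfg <- lapply(seq_along(per_fn), function(j)
      per_fn[[j]][[combos[i, j]]])
    names(cfg) <- names(space$functionalities)
    structure(cfg, class = "configuration")
  })
}

#' @export
print.configuration <- function(x, ...) {
  cat("<configuration>\n")
  for (fid in names(x)) {
    ch <- x[[fid]]
    ptxt <- if (length(ch$params))
      paste0(" (", paste(names(ch$params), unlist(ch$params),
                         sep = "=", collapse = ", "), ")")
    else ""
    cat("  ", fid, ": ", ch$component, ptxt, "\n", sep = "")
  }
  invisible(x)
}

#' Metric vector of a configuration evaluation
#'
#' Benefits (precision P, recall R, maximised) and costs (execution time ET,
#' energy EC, memory demand MD, communication latency CL, minimised).
#'
#' @param P,R fractions in [0, 1].
#' @param ET seconds.
#' @param EC mWh.
#' @param MD bytes.
#' @param CL seconds.
#' @return A named numeric vector of class `metric_vector`.
#' @export
metric_vector <- function(P, R, ET, EC, MD, CL = 0) {
  v <- c(P = P, R = R, ET = ET, EC = EC, MD = MD, CL = CL)
  if (P < 0 || P > 1 || R < 0 || R > 1)
    stop("P and R must lie in [0, 1]")
  if (any(v[c("ET", "EC", "MD", "CL")] < 0))
    stop("cost metrics must be non-negative")
  structure(v, class = "metric_vector")
}

.benefit_names <- c("P", "R")
.cost_names <- c("ET", "EC", "MD", "CL")

#' Pareto dominance between metric vectors
#'
#' `a` dominates `b` when it is at least as good in every objective
#' (higher-or-equal benefits, lower-or-equal costs) and strictly better in
#' at least one.
#'
#' @param a,b `metric_vector`s over the same objective set.
#' @return Logical.
#' @export
dominates <- function(a, b) {
  stopifnot(inherits(a, "metric_vector"), inherits(b, "metric_vector"))
  if (!identical(names(a), names(b)))
    stop("metric vectors carry different objective sets")
  # orient all objectives as "larger is better"
  oa <- c(a[.benefit_names], -a[.cost_names])
  ob <- c(b[.benefit_names], -b[.cost_names])
  all(oa >= ob) && any(oa > ob)
}

#' Non-dominated subset of a list of metric vectors
#'
#' @param vectors non-empty list of `metric_vector`s.
#' @return The sublist of members dominated by no other member, in stable
#'   input order.
#' @export
pareto_front <- function(vectors) {
  if (length(vectors) == 0) stop("empty metric-vector list")
  keep <- vapply(seq_along(vectors), function(i) {
    !any(vapply(seq_along(vectors), function(j)
      j != i && dominates(vectors[[j]], vectors[[i]]), logical(1)))
  }, logical(1))
  vectors[keep]
}

#' System requirements
#'
#' Benefit thresholds (minimum precision/recall) and cost bounds (execution
#' time, energy budget, memory capacity and optionally latency tolerance).
#' The execution-time bound is the frame length m in real-time mode or the
#' runtime T in online mode. The default energy budget derives from the
#' shipped battery via [energy_requirement()]; pass `energy_budget` to
#' override (e.g. with a datasheet-rounded figure).
#'
#' @param min_precision,min_recall fractions in (0, 1].
#' @param et_bound_s execution-time bound in seconds.
#' @param energy_budget_mWh energy budget in mWh.
#' @param memory_capacity_bytes memory bound in bytes.
#' @param latency_tolerance_s optional latency bound in seconds; `NULL`
#'   (default) excludes CL from the feasibility conjunction.
#' @return A `requirement_set`.
#' @export
requirement_set <- function(min_precision = 0.70, min_recall = 0.80,
                            et_bound_s, energy_budget_mWh =
                              energy_requirement(hardware_profiles()$battery),
                            memory_capacity_bytes,
                            latency_tolerance_s = NULL) {
  stopifnot(min_precision > 0, min_precision <= 1,
            min_recall > 0, min_recall <= 1,
            et_bound_s > 0, energy_budget_mWh > 0,
            memory_capacity_bytes > 0)
  if (!is.null(latency_tolerance_s)) stopifnot(latency_tolerance_s > 0)
  structure(list(min_precision = min_precision, min_recall = min_recall,
                 et_bound_s = et_bound_s,
                 energy_budget_mWh = energy_budget_mWh,
                 memory_capacity_bytes = memory_capacity_bytes,
                 latency_tolerance_s = latency_tolerance_s),
            class = "requirement_set")
}

#' Select the optimal feasible configuration
#'
#' The constrained multi-objective problem is relaxed to maximising the sum
#' of benefits over the feasible set (all requirement-normalised costs <= 1
#' and benefits >= 1). Ties are broken by lower total energy, then by
#' enumeration order.
#'
#' @param evaluated list of `list(configuration = , metrics = )` pairs in
#'   enumeration order.
#' @param req a [requirement_set()].
#' @return The winning element of `evaluated`, or `NULL` when no
#'   configuration is feasible.
#' @export
select_optimal <- function(evaluated, req) {
  stopifnot(inherits(req, "requirement_set"))
  if (length(evaluated) == 0) return(NULL)
  feas <- vapply(evaluated, function(e)
    normalize_metrics(e$metrics, req)$feasible, logical(1))
  if (!any(feas)) return(NULL)
  idx <- which(feas)
  benefit <- vapply(idx, function(i)
    sum(evaluated[[i]]$metrics[.benefit_names]), numeric(1))
  ec <- vapply(idx, function(i) evaluated[[i]]$metrics[["EC"]], numeric(1))
  # order: max benefit, then min EC, then enumeration order
  best <- idx[order(-benefit, ec, idx)][1]
  evaluated[[best]]
}
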