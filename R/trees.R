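#' Directed-tree multistate model with constant transition hazards
#'
#' The event-history model behind both estimation and simulation is a
#' multistate model whose states form a directed tree: every state
#' corresponds to a unique sequence of component events, so state-occupation
#' probabilities of the non-root states are exactly the exhaustive
#' event-type probabilities. Each edge is labelled by the component that
#' occurs on it and optionally carries a constant transition hazard (per
#' unit of follow-up time).
#'
#' @param edges Data frame with columns `from`, `to`, `component` and
#'   optionally `hazard` (constant rate, >= 0).
#' @param root Label of the initial state. Defaults to the unique state that
#'   never appears in `to`.
#' @return A `wc_tree` object: `edges` (tibble), `states` (character, root
#'   first, parents before children), `root`.
#' @examples
#' tree_illness_death()
#' @export
multistate_tree <- function(edges, root = NULL) {
  edges <- as_tibble(edges)
  need <- c("from", "to", "component")
  if (length(setdiff(need, names(edges)))) {
    stop_wcomp("edges need columns from, to, component")
  }
  if (!"hazard" %in% names(edges)) edges$hazard <- NA_real_
  if (any(!is.na(edges$hazard) & (edges$hazard < 0 | !is.finite(edges$hazard)))) {
    stop_wcomp("hazards must be finite and non-negative")
  }
  if (anyDuplicated(edges$to)) {
    stop_wcomp("not a directed tree: some state has more than one parent")
  }
  roots <- setdiff(edges$from, edges$to)
  if (is.null(root)) {
    if (length(roots) != 1) stop_wcomp("tree must have exactly one root (found: %s)",
                                       paste(roots, collapse = ", "))
    root <- roots
  } else if (!identical(sort(roots), sort(root))) {
    stop_wcomp("declared root does not match edge structure")
  }
  # topological order by repeated frontier expansion; also detects cycles
  states <- root
  repeat {
    nxt <- edges$to[edges$from %in% states & !(edges$to %in% states)]
    if (!length(nxt)) break
    states <- c(states, unique(nxt))
  }
  if (length(states) != length(unique(c(edges$from, edges$to)))) {
    stop_wcomp("edges contain states unreachable from the root")
  }
  structure(list(edges = edges, states = states, root = root),
            class = "wc_tree")
}

#' @export
print.wc_tree <- function(x, ...) {
  cat(sprintf("<wc_tree: %d states, root '%s'>\n", length(x$states), x$root))
  print(x$edges, n = nrow(x$edges))
  invisible(x)
}

# component sequence (root -> state) for every non-root state, as a named list
tree_paths <- function(tree) {
  e <- tree$edges
  paths <- list()
  for (s in tree$states) {
    if (s == tree$root) next
    row <- which(e$to == s)
    parent <- e$from[row]
    prev <- if (parent == tree$root) character(0) else paths[[parent]]
    paths[[s]] <- c(prev, e$component[row])
  }
  paths
}

# map tree (with components) to its canonical scheme-building pieces
tree_components <- function(tree, fatal = NULL) {
  comps <- unique(tree$edges$component)
  leaf <- setdiff(tree$states, tree$edges$from)
  if (is.null(fatal)) {
    # a component is treated as absorbing when every edge carrying it ends
    # in a leaf state
    fatal <- vapply(comps, function(cp) {
      all(tree$edges$to[tree$edges$component == cp] %in% leaf)
    }, logical(1))
  }
  component_set(comps, fatal)
}

#' Intensity matrix of a constant-hazard tree
#'
#' @param tree A [multistate_tree()] with hazards on all edges.
#' @return Square generator matrix over `tree$states`.
#' @keywords internal
tree_generator <- function(tree) {
  if (anyNA(tree$edges$hazard)) stop_wcomp("tree has edges without hazards")
  S <- length(tree$states)
  Q <- matrix(0, S, S, dimnames = list(tree$states, tree$states))
  for (i in seq_len(nrow(tree$edges))) {
    Q[tree$edges$from[i], tree$edges$to[i]] <- tree$edges$hazard[i]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Exact event-type probabilities of a constant-hazard tree
#'
#' Solves the Kolmogorov forward equations of the directed-tree model by
#' matrix exponentiation and returns state-occupation probabilities at time
#' `t`, optionally mapped into an event-type scheme. Serves as the analytic
#' oracle for the simulator and for power calculations.
#'
#' @param tree A [multistate_tree()] with hazards.
#' @param t Time point (or vector of time points).
#' @param scheme Optional [build_scheme()]; when supplied the result has one
#'   row per event type of the scheme, otherwise one row per tree state
#'   (including the root, whose probability is 1 minus the any-event
#'   probability).
#' @return A tibble with columns `t`, `state`/`event_type`, `prob`.
#' @examples
#' analytic_event_probs(tree_illness_death(), t = 5)
#' @export
analytic_event_probs <- function(tree, t, scheme = NULL) {
  Q <- tree_generator(tree)
  rows <- lapply(t, function(tt) {
    p <- as.numeric(Matrix::expm(Q * tt)[tree$root, ])
    names(p) <- tree$states
    if (is.null(scheme)) {
      tibble(t = tt, state = tree$states, prob = p)
    } else {
      p_ex <- drop(state_aggregation(tree, scheme) %*% p[tree$states])
      tibble(t = tt, event_type = scheme$event_types,
             prob = drop(scheme$L %*% p_ex))
    }
  })
  bind_rows(rows)
}

# K_ex x S matrix collapsing tree states onto exhaustive event types
state_aggregation <- function(tree, scheme) {
  labs <- scheme$components$component
  paths <- tree_paths(tree)
  keys <- vapply(scheme$exhaustive_subsets, function(idx)
    paste(sort(labs[idx]), collapse = "."), character(1))
  M <- matrix(0, length(keys), length(tree$states),
              dimnames = list(keys, tree$states))
  for (s in names(paths)) {
    key <- paste(sort(paths[[s]]), collapse = ".")
    j <- match(key, keys)
    if (is.na(j)) stop_wcomp("tree state '%s' has no matching exhaustive event type", s)
    M[j, s] <- 1
  }
  M
}

#' Bundled multistate models
#'
#' `tree_illness_death()` is an illness-death model with a non-fatal state N
#' and a fatal state F (transitions initial->N, initial->F, N->F).
#' `tree_two_transient()` has two transient states N and M (M more severe)
#' and a fatal state F reachable directly or after either transient event.
#' `tree_cardiovascular()` is a vascular-prevention model with non-fatal
#' myocardial infarction (MI), non-fatal stroke (ST) and vascular death
#' (DE); post-MI transition rates are doubled relative to the initial rates
#' and strokes are not followed by MI.
#'
#' The default rates (per year) are the trial scenarios used throughout the
#' package's simulation studies.
#'
#' @param rates Named or positional numeric vector of constant hazards; see
#'   each function's signature for the edge order.
#' @param arm For `tree_cardiovascular()`: `"control"` or `"intervention"`
#'   selects the corresponding published rate set (ignored when `rates` is
#'   supplied).
#' @return A [multistate_tree()].
#' @name bundled_trees
NULL

#' @rdname bundled_trees
#' @export
tree_illness_death <- function(rates = c(nonfatal = 0.05, fatal = 0.02,
                                         fatal_after_nonfatal = 0.2)) {
  multistate_tree(tibble(
    from = c("initial", "initial", "N"),
    to = c("N", "F", "N.F"),
    component = c("N", "F", "F"),
    hazard = as.numeric(rates)))
}

#' @rdname bundled_trees
#' @export
tree_two_transient <- function(rates = c(0.08, 0.1, 0.04, 0.2, 0.3)) {
  multistate_tree(tibble(
    from = c("initial", "initial", "initial", "N", "M"),
    to = c("N", "M", "F", "N.F", "M.F"),
    component = c("N", "M", "F", "F", "F"),
    hazard = as.numeric(rates)))
}

#' @rdname bundled_trees
#' @export
tree_cardiovascular <- function(arm = c("control", "intervention"),
                                rates = NULL) {
  arm <- arg_match(arm)
  if (is.null(rates)) {
    rates <- if (arm == "control") c(0.04, 0.06, 0.015, 0.12, 0.03, 0.03)
             else c(0.03, 0.04, 0.01, 0.08, 0.02, 0.02)
  }
  r <- as.numeric(rates)
  # r: initial->MI, initial->ST, initial->DE, MI->ST, MI->DE, ST->DE;
  # the post-MI stroke state keeps the doubled stroke-death rate r[6]
  multistate_tree(tibble(
    from = c("initial", "initial", "initial", "MI", "MI", "ST", "MI.ST"),
    to = c("MI", "ST", "DE", "MI.ST", "MI.DE", "ST.DE", "MI.ST.DE"),
    component = c("MI", "ST", "DE", "ST", "DE", "DE", "DE"),
    hazard = c(r[1:6], r[6])))
}

#' Scale hazards of a tree
#'
#' Multiplies the hazard of selected edges (default: all) by a factor;
#' used to derive intervention arms with proportional rate reductions.
#'
#' @param tree A [multistate_tree()].
#' @param factor Positive multiplier.
#' @param edges Optional integer or logical index into `tree$edges` rows.
#' @export
scale_hazards <- function(tree, factor, edges = NULL) {
  if (is.null(edges)) edges <- seq_len(nrow(tree$edges))
  tree$edges$hazard[edges] <- tree$edges$hazard[edges] * factor
  tree
}
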