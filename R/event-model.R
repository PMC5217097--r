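#' Define the component outcomes of a composite endpoint
#'
#' A component set lists the distinct clinical events (components) that make
#' up a composite endpoint, in increasing order of severity, together with a
#' flag marking which components are absorbing (fatal): an absorbing
#' component ends a subject's event history.
#'
#' @param labels Character vector of component names, ordered from least to
#'   most severe (the severity ranking is used by the worst-event scheme and
#'   by [cone_ordered()]).
#' @param fatal Logical vector of the same length; `TRUE` for absorbing
#'   components. Recycled if length 1.
#' @return A `wc_components` tibble with columns `component`, `fatal` and
#'   `severity` (1 = least severe).
#' @examples
#' component_set(c("N", "F"), fatal = c(FALSE, TRUE))
#' @export
component_set <- function(labels, fatal = FALSE) {
  if (length(labels) == 0) stop_wcomp("component set must not be empty")
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop_wcomp("component labels must be unique")
  if ("censor" %in% labels) stop_wcomp("'censor' is a reserved event label")
  fatal <- rep_len(as.logical(fatal), length(labels))
  out <- tibble(component = labels, fatal = fatal,
                severity = seq_along(labels))
  class(out) <- c("wc_components", class(out))
  out
}

# All component subsets reachable as event histories: non-fatal components in
# any order, at most one fatal component and only as the final event.
# Returned as a list of character vectors ordered by (size, severity profile).
reachable_subsets <- function(components) {
  labs <- components$component
  fatal <- components$fatal
  K <- length(labs)
  subsets <- list()
  for (m in 1:(2^K - 1)) {
    idx <- which(bitwAnd(m, 2^(seq_len(K) - 1)) > 0)
    if (sum(fatal[idx]) > 1) next
    subsets[[length(subsets) + 1]] <- idx
  }
  order_subsets(subsets, labs)
}

order_subsets <- function(subsets, labs) {
  # sort by size, then lexicographically by decreasing severity ranks so that
  # e.g. {N},{F},{N,F} and {N},{M},{F},{N,F},{M,F} come out in severity order
  keys <- vapply(subsets, function(idx) {
    sev <- sort(idx, decreasing = TRUE)
    paste0(length(idx), "-", paste(sprintf("%03d", sev), collapse = "."))
  }, character(1))
  subsets[order(keys)]
}

subset_label <- function(idx, labs) paste(labs[sort(idx)], collapse = ".")

#' Build an event-type scheme
#'
#' An event-type scheme fixes the categories of patient outcome over a
#' horizon `(0, tau]` to which weights are attached, and the 0/1 matrix `L`
#' that maps exhaustive event-type probabilities onto the scheme's
#' probabilities.
#'
#' Four settings are supported:
#' * `"exhaustive"`: one type per realized combination of components
#'   (the no-event category is always excluded, so the covariance of the
#'   estimated probabilities has full rank);
#' * `"competing_risks"`: one type per possible *first* event;
#' * `"worst_event"`: one type per possible most severe realized component;
#' * `"marginal"`: one (possibly overlapping) type per component.
#'
#' If a [multistate_tree()] is supplied the exhaustive types are the distinct
#' component sets reachable in the tree; otherwise all combinations
#' compatible with the fatal flags are used.
#'
#' @param components A [component_set()].
#' @param setting One of `"exhaustive"`, `"competing_risks"`,
#'   `"worst_event"`, `"marginal"`.
#' @param tree Optional [multistate_tree()] restricting which component
#'   combinations are reachable (required for `"competing_risks"` with more
#'   than one non-fatal component).
#' @return A `wc_scheme` object with fields `setting`, `event_types`, `L`,
#'   `exhaustive_types`, `K`.
#' @examples
#' nf <- component_set(c("N", "F"), fatal = c(FALSE, TRUE))
#' build_scheme(nf, "marginal")$L
#' @export
build_scheme <- function(components,
                         setting = c("exhaustive", "competing_risks",
                                     "worst_event", "marginal"),
                         tree = NULL) {
  setting <- arg_match(setting)
  if (!inherits(components, "wc_components")) {
    stop_wcomp("`components` must be created by component_set()")
  }
  labs <- components$component
  fatal <- components$fatal

  if (is.null(tree)) {
    subsets <- reachable_subsets(components)
    first_comp <- vapply(subsets, function(idx) {
      nonfatal <- idx[!fatal[idx]]
      if (length(idx) == 1) idx else if (length(nonfatal) == 1) nonfatal else NA_integer_
    }, integer(1))
  } else {
    info <- tree_subsets(tree, components)
    subsets <- info$subsets
    first_comp <- info$first_comp
  }
  ex_labels <- unname(vapply(subsets, subset_label, character(1), labs = labs))
  K_ex <- length(subsets)

  worst <- vapply(subsets, max, integer(1))  # severity index of worst member

  build_L <- function(rows_idx, member_fun) {
    L <- matrix(0, length(rows_idx), K_ex)
    for (r in seq_along(rows_idx)) {
      L[r, ] <- vapply(seq_len(K_ex), function(j) {
        as.numeric(member_fun(rows_idx[r], j))
      }, numeric(1))
    }
    L
  }

  if (setting == "exhaustive") {
    types <- ex_labels
    L <- diag(1, K_ex)
  } else if (setting == "marginal") {
    types <- labs
    L <- build_L(seq_along(labs), function(c_i, j) c_i %in% subsets[[j]])
  } else if (setting == "worst_event") {
    present <- sort(unique(worst))
    types <- labs[present]
    L <- build_L(present, function(c_i, j) worst[j] == c_i)
  } else { # competing_risks
    if (anyNA(first_comp)) {
      stop_wcomp(paste0(
        "first event is ambiguous for some component combinations; ",
        "supply a multistate tree to build a competing-risks scheme"))
    }
    present <- sort(unique(first_comp))
    types <- labs[present]
    L <- build_L(present, function(c_i, j) first_comp[j] == c_i)
  }

  structure(
    list(setting = setting, event_types = types, L = L,
         exhaustive_types = ex_labels, exhaustive_subsets = subsets,
         components = components, K = length(types)),
    class = "wc_scheme")
}

# component subsets and first components of the non-root states of a tree,
# collapsed to distinct subsets; errors if two states share a subset but
# disagree on the first component (first event would be ambiguous)
tree_subsets <- function(tree, components) {
  labs <- components$component
  paths <- tree_paths(tree)
  idx_list <- lapply(paths, function(p) sort(match(p, labs)))
  if (anyNA(unlist(idx_list))) {
    stop_wcomp("tree components not all present in the component set")
  }
  keys <- vapply(idx_list, paste, character(1), collapse = ".")
  firsts <- vapply(paths, function(p) match(p[1], labs), integer(1))
  uk <- !duplicated(keys)
  subsets <- idx_list[uk]
  first_comp <- firsts[uk]
  for (k in unique(keys)) {
    f <- unique(firsts[keys == k])
    if (length(f) > 1) first_comp[match(k, keys[uk])] <- NA_integer_
  }
  ord <- order_subsets(subsets, labs)
  reord <- match(vapply(ord, paste, character(1), collapse = "."),
                 vapply(subsets, paste, character(1), collapse = "."))
  list(subsets = subsets[reord], first_comp = first_comp[reord])
}

#' @export
print.wc_scheme <- function(x, ...) {
  cat(sprintf("<wc_scheme: %s, %d event type(s)>\n", x$setting, x$K))
  cat("event types:", paste(x$event_types, collapse = ", "), "\n")
  cat("exhaustive types:", paste(x$exhaustive_types, collapse = ", "), "\n")
  invisible(x)
}

#' Classify subjects into event types over a fixed horizon
#'
#' Turns subject-level event histories with complete follow-up through
#' `tau` into 0/1 event-type indicators under a scheme. Events at exactly
#' `tau` count as inside the closed interval `(0, tau]`.
#'
#' @param data Event-history data frame (see [read_event_history()] for the
#'   format): columns `id`, `arm`, `time`, `event`.
#' @param scheme A [build_scheme()] scheme.
#' @param tau Follow-up horizon (> 0).
#' @return A tibble with one row per subject: `id`, `arm`, and one 0/1
#'   column per event type of the scheme.
#' @export
classify_events <- function(data, scheme, tau) {
  core <- classify_core(data, scheme, tau)
  ind <- core$ex_ind %*% t(scheme$L)
  colnames(ind) <- scheme$event_types
  as_tibble(cbind(tibble(id = core$ids, arm = core$arms),
                  as_tibble(as.data.frame(ind))))
}

# fast vectorized classification into exhaustive event types; errors on
# incomplete follow-up. Returns ids, arms and the n x K_ex indicator matrix.
classify_core <- function(data, scheme, tau) {
  validate_history(data)
  if (tau <= 0) stop_wcomp("`tau` must be positive")
  comps <- scheme$components
  labs <- comps$component

  ids <- unique(data$id)
  n <- length(ids)
  si <- match(data$id, ids)
  arms <- data$arm[match(ids, data$id)]

  evsel <- data$event != "censor" & data$time <= tau
  ci <- match(data$event[evsel], labs)
  if (anyNA(ci)) {
    stop_wcomp("unknown event label(s): %s",
               paste(unique(data$event[evsel][is.na(ci)]), collapse = ", "))
  }
  # completeness: absorbed by tau, or observed through tau
  absorbed <- logical(n)
  if (any(evsel)) {
    fat <- comps$fatal[ci]
    absorbed[unique(si[evsel][fat])] <- TRUE
  }
  end_time <- vapply(split(data$time, si), max, numeric(1))
  incomplete <- !absorbed & end_time < tau - 1e-12
  if (any(incomplete)) {
    stop_wcomp(paste0(
      "subject(s) censored before tau without an absorbing event: ",
      paste(head(ids[incomplete], 5), collapse = ", "),
      "; incomplete follow-up; use the Aalen-Johansen path"))
  }

  keys <- vapply(scheme$exhaustive_subsets, paste, character(1), collapse = ".")
  ex_ind <- matrix(0, n, length(keys))
  if (any(evsel)) {
    o <- order(si[evsel], ci)
    sj <- si[evsel][o]
    cj <- ci[o]
    subject_keys <- vapply(split(cj, sj), paste, character(1), collapse = ".")
    who <- as.integer(names(subject_keys))
    j <- match(subject_keys, keys)
    if (anyNA(j)) {
      bad <- subject_keys[is.na(j)][1]
      stop_wcomp("component combination '%s' is not an exhaustive event type",
                 paste(labs[as.integer(strsplit(bad, ".", fixed = TRUE)[[1]])],
                       collapse = "."))
    }
    ex_ind[cbind(who, j)] <- 1
  }
  list(ids = ids, arms = arms, ex_ind = ex_ind, n = n)
}

# shared validation of the long event-history format (vectorized)
validate_history <- function(data) {
  need <- c("id", "arm", "time", "event")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_wcomp("event history lacks column(s): %s",
                               paste(miss, collapse = ", "))
  if (nrow(data) == 0) stop_wcomp("event history is empty")
  if (any(data$time <= 0)) stop_wcomp("event times must be strictly positive")
  if (anyDuplicated(paste(data$id, data$time, sep = "\r"))) {
    stop_wcomp("tied transition times within a subject are not valid input")
  }
  is_cen <- data$event == "censor"
  if (any(is_cen)) {
    cen_id <- data$id[is_cen]
    if (anyDuplicated(cen_id)) {
      stop_wcomp("subject '%s' has more than one censor row",
                 cen_id[duplicated(cen_id)][1])
    }
    # censor row must be the subject's last observation
    mx <- tapply(data$time, data$id, max)
    late <- data$time[is_cen] < mx[cen_id] - 1e-12
    if (any(late)) {
      stop_wcomp("subject '%s' has events after its censor row", cen_id[late][1])
    }
  }
  invisible(data)
}
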