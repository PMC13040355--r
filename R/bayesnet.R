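#' Construct a discrete Bayesian network specification
#'
#' A light container for a directed acyclic network over discretized
#' behavioural variables plus the class node. Conditional probability tables
#' are long-format data frames: one column per parent, a `value` column for
#' the node's own state and a `prob` column; probabilities must sum to 1
#' within each parent configuration.
#'
#' @param nodes named list mapping node name to its domain (character vector
#'   of states).
#' @param edges two-column data frame (`from`, `to`) of directed edges; may be
#'   empty.
#' @param cpts named list of CPT data frames, one per node.
#' @return an object of class `bn_spec`.
#' @examples
#' nodes <- list(class = c("yes", "no"), x = c("hi", "lo"))
#' edges <- data.frame(from = "class", to = "x")
#' cpts <- list(
#'   class = data.frame(value = c("yes", "no"), prob = c(0.3, 0.7)),
#'   x = data.frame(class = c("yes", "yes", "no", "no"),
#'                  value = c("hi", "lo", "hi", "lo"),
#'                  prob = c(0.9, 0.1, 0.2, 0.8)))
#' spec <- bn_spec(nodes, edges, cpts)
#' bn_joint(spec, list(class = "yes", x = "hi"))  # 0.27
#' @export
bn_spec <- function(nodes, edges, cpts) {
  if (is.null(names(nodes)) || any(names(nodes) == "")) {
    abort("`nodes` must be a fully named list of domains")
  }
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0 && !all(c("from", "to") %in% names(edges))) {
    abort("`edges` must have columns 'from' and 'to'")
  }
  unknown <- setdiff(unique(c(edges$from, edges$to)), names(nodes))
  if (length(unknown) > 0) {
    abort(paste("edges reference unknown node(s):",
                paste(unknown, collapse = ", ")))
  }
  # acyclicity by Kahn's algorithm
  order <- bn_topo_order(names(nodes), edges)
  if (is.null(order)) abort("edge list contains a cycle")
  parents <- lapply(setNames(names(nodes), names(nodes)), function(nd) {
    edges$from[edges$to == nd]
  })
  for (nd in names(nodes)) {
    cpt <- cpts[[nd]]
    if (is.null(cpt)) abort(sprintf("missing CPT for node '%s'", nd))
    need <- c(parents[[nd]], "value", "prob")
    if (!all(need %in% names(cpt))) {
      abort(sprintf("CPT for '%s' must have columns %s", nd,
                    paste(need, collapse = ", ")))
    }
    key <- if (length(parents[[nd]]) > 0) {
      interaction(cpt[parents[[nd]]], drop = TRUE)
    } else factor(rep("", nrow(cpt)))
    sums <- tapply(cpt$prob, key, sum)
    if (any(abs(sums - 1) > 1e-9)) {
      abort(sprintf("CPT rows for node '%s' do not sum to 1", nd))
    }
  }
  structure(list(nodes = nodes, edges = edges, parents = parents,
                 cpts = cpts, order = order), class = "bn_spec")
}

bn_topo_order <- function(nodes, edges) {
  indeg <- setNames(integer(length(nodes)), nodes)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  out <- character(0)
  queue <- names(indeg)[indeg == 0]
  edges_left <- edges
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    ch <- edges_left$to[edges_left$from == v]
    edges_left <- edges_left[edges_left$from != v, , drop = FALSE]
    for (u in ch) {
      indeg[u] <- indeg[u] - 1L
      if (indeg[u] == 0) queue <- c(queue, u)
    }
  }
  if (length(out) == length(nodes)) out else NULL
}

#' Joint probability of a full assignment under a Bayesian network
#'
#' Multiplies, over every node, the CPT probability of the node's value given
#' its parents' values in `assignment`.
#'
#' @param spec a [bn_spec()] object.
#' @param assignment named list or character vector assigning a state to
#'   every node.
#' @return joint probability (numeric scalar).
#' @export
bn_joint <- function(spec, assignment) {
  stopifnot(inherits(spec, "bn_spec"))
  assignment <- as.list(assignment)
  missing <- setdiff(names(spec$nodes), names(assignment))
  if (length(missing) > 0) {
    abort(sprintf("assignment missing node '%s'", missing[1]))
  }
  prob <- 1
  for (nd in names(spec$nodes)) {
    val <- as.character(assignment[[nd]])
    if (!val %in% spec$nodes[[nd]]) {
      abort(sprintf("value '%s' outside domain of node '%s'", val, nd))
    }
    cpt <- spec$cpts[[nd]]
    sel <- rep(TRUE, nrow(cpt))
    for (p in spec$parents[[nd]]) {
      sel <- sel & cpt[[p]] == as.character(assignment[[p]])
    }
    if (!any(sel)) {
      abort(sprintf("zero-probability parent configuration at node '%s'", nd))
    }
    row <- sel & cpt$value == val
    prob <- prob * if (any(row)) cpt$prob[row][1] else 0
  }
  prob
}

#' Posterior over the class node by enumeration
#'
#' @param spec a [bn_spec()] object.
#' @param evidence named assignment of every non-class node.
#' @param class_node name of the class node (default `"class"`).
#' @return named numeric vector of posterior probabilities over the class
#'   domain.
#' @export
bn_posterior <- function(spec, evidence, class_node = "class") {
  states <- spec$nodes[[class_node]]
  joint <- vapply(states, function(s) {
    assignment <- c(setNames(list(s), class_node), as.list(evidence))
    bn_joint(spec, assignment)
  }, numeric(1))
  if (sum(joint) == 0) abort("evidence has probability zero under the network")
  joint / sum(joint)
}

#' Discretize features into training-quartile bins
#'
#' @param x numeric vector.
#' @param breaks cut points (interior); values are binned with `findInterval`.
#' @return character vector of bin labels `"q1"..`.
#' @export
discretize_quartile <- function(x, breaks) {
  paste0("q", findInterval(x, breaks) + 1L)
}

#' Fit a naive-structure Bayesian network from a design matrix
#'
#' Commits to the naive structure (class as sole parent of each discretized
#' feature) since no dependency structure among the behavioural variables is
#' published; arbitrary DAGs can still be supplied directly to [bn_spec()].
#' Features are discretized at training-data quartiles and CPTs estimated
#' with Laplace smoothing.
#'
#' @param data a `design_matrix` with a `label` column.
#' @param features feature columns to include (default all of
#'   [feature_names()]).
#' @param alpha Laplace smoothing pseudo-count (default 1).
#' @return list with the fitted `spec`, the per-feature `breaks`, and the
#'   class node name (`"class"`).
#' @export
bn_fit_naive <- function(data, features = feature_names(), alpha = 1) {
  y <- data$label
  classes <- sort(unique(y))
  breaks <- lapply(setNames(features, features), function(f) {
    unique(quantile(data[[f]], probs = c(0.25, 0.5, 0.75), names = FALSE))
  })
  nodes <- c(list(class = classes),
             lapply(breaks, function(b) paste0("q", seq_len(length(b) + 1))))
  names(nodes) <- c("class", features)
  edges <- data.frame(from = "class", to = features)
  cpts <- list(class = data.frame(
    value = classes,
    prob = as.numeric(table(factor(y, classes)) + alpha) /
      (length(y) + alpha * length(classes))))
  for (f in features) {
    binned <- discretize_quartile(data[[f]], breaks[[f]])
    dom <- nodes[[f]]
    tab <- table(factor(y, classes), factor(binned, dom)) + alpha
    tab <- tab / rowSums(tab)
    cpts[[f]] <- data.frame(
      class = rep(classes, times = length(dom)),
      value = rep(dom, each = length(classes)),
      prob = as.numeric(tab))
  }
  list(spec = bn_spec(nodes, edges, cpts), breaks = breaks,
       class_node = "class")
}

#' Score accounts with the naive Bayesian network
#'
#' @param bn result of [bn_fit_naive()].
#' @param data a `design_matrix` of accounts to score.
#' @param positive class state whose posterior is returned (default
#'   `"abnormal"`).
#' @return tibble with `account_id` and `bn_posterior`.
#' @export
bn_score <- function(bn, data, positive = "abnormal") {
  feats <- names(bn$breaks)
  binned <- lapply(feats, function(f) {
    discretize_quartile(data[[f]], bn$breaks[[f]])
  })
  names(binned) <- feats
  post <- vapply(seq_len(nrow(data)), function(i) {
    ev <- lapply(binned, `[[`, i)
    bn_posterior(bn$spec, ev, class_node = bn$class_node)[[positive]]
  }, numeric(1))
  tibble(account_id = data$account_id, bn_posterior = post)
}
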