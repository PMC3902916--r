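#' Screen candidate regulator-target pairs kinetically
#'
#' Every requested (regulator, target) pair is fitted with [anneal_fit()];
#' an edge is accepted when the fit correlation exceeds 0.8, or 0.65 when a
#' prior interaction (ChIP or literature) supports the pair. Self-pairs are
#' skipped. Edges are alternatives: several accepted regulators of one
#' target are all reported, never merged.
#'
#' @param regulators Numeric matrix of regulator profiles (rows named by
#'   regulator id) or a named list of profiles.
#' @param targets Matrix of target (gene or cluster-core) profiles, rows
#'   named.
#' @param grid A [time_grid()].
#' @param priors Optional data frame with columns `regulator_id`,
#'   `target_id`, `source` (`"chip"` or `"literature"`).
#' @param config A [fit_config()]; defaults to [screening_config()].
#' @param r_accept Acceptance threshold without prior (strict); default 0.8.
#' @param r_accept_prior Acceptance threshold with prior (strict); default
#'   0.65.
#' @param r_trivial Trivial-regulation threshold; default 0.9.
#' @param target_kind Label stored on the edges (`"gene"`, `"cluster"` or
#'   `"sigma"`).
#' @param keep_all Also return rejected pairs (with `accepted = FALSE`).
#' @return Data frame of edges: regulator_id, target_id, target_kind, k1,
#'   k2, w, b, correlation, F, trivial, prior_source, accepted_threshold,
#'   accepted.
#' @export
screen_regulations <- function(regulators, targets, grid = time_grid(),
                               priors = NULL, config = screening_config(),
                               r_accept = 0.8, r_accept_prior = 0.65,
                               r_trivial = 0.9, target_kind = "gene",
                               keep_all = FALSE) {
  regulators <- .as_profile_matrix(regulators, grid)
  targets <- .as_profile_matrix(targets, grid)
  if (!is.null(priors)) {
    stopifnot(all(c("regulator_id", "target_id", "source") %in%
                    names(priors)))
    # priors may cover a larger universe than this screen
    priors <- priors[priors$regulator_id %in% rownames(regulators), ,
                     drop = FALSE]
  }
  rows <- list()
  for (rg in rownames(regulators)) {
    for (tg in rownames(targets)) {
      if (identical(rg, tg)) next
      prior <- .prior_source(priors, rg, tg)
      fit <- anneal_fit(targets[tg, ], regulators[rg, ], grid, config)
      thr <- if (prior == "none") r_accept else r_accept_prior
      accepted <- is.finite(fit$correlation) && fit$correlation > thr
      if (!accepted && !keep_all) next
      rows[[length(rows) + 1L]] <- data.frame(
        regulator_id = rg, target_id = tg, target_kind = target_kind,
        k1 = fit$params[["k1"]], k2 = fit$params[["k2"]],
        w = fit$params[["w"]], b = fit$params[["b"]],
        correlation = fit$correlation, F = fit$F,
        trivial = classify_trivial(regulators[rg, ], targets[tg, ],
                                   r_trivial),
        prior_source = prior, accepted_threshold = thr, accepted = accepted,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_edges())
  do.call(rbind, rows)
}

.as_profile_matrix <- function(x, grid) {
  if (is.list(x) && !is.data.frame(x))
    x <- do.call(rbind, x)
  stopifnot(is.matrix(x), ncol(x) == nrow(grid), !is.null(rownames(x)))
  x
}

.prior_source <- function(priors, rg, tg) {
  if (is.null(priors)) return("none")
  hit <- priors$regulator_id == rg & priors$target_id == tg
  if (!any(hit)) return("none")
  src <- priors$source[hit]
  if ("chip" %in% src) "chip" else src[1]
}

.empty_edges <- function() {
  data.frame(regulator_id = character(), target_id = character(),
             target_kind = character(), k1 = numeric(), k2 = numeric(),
             w = numeric(), b = numeric(), correlation = numeric(),
             F = numeric(), trivial = logical(), prior_source = character(),
             accepted_threshold = numeric(), accepted = logical(),
             mutual = logical(), preferred = logical(),
             stringsAsFactors = FALSE)
}

#' Screen the sigma-sigma regulatory network
#'
#' All ordered pairs of sigma-factor profiles are screened; when both
#' directions of a pair are accepted and both are trivial (the profiles are
#' themselves highly correlated), the pair is flagged mutual. If a prior
#' supports exactly one direction of a mutual pair, that direction is marked
#' preferred; both edges are retained.
#'
#' @inheritParams screen_regulations
#' @param sigma_profiles Matrix of sigma-factor profiles, rows named.
#' @return Edge data frame as in [screen_regulations()] with added logical
#'   columns `mutual` and `preferred`.
#' @export
sigma_sigma_network <- function(sigma_profiles, grid = time_grid(),
                                priors = NULL, config = screening_config(),
                                r_accept = 0.8, r_accept_prior = 0.65,
                                r_trivial = 0.9) {
  sigma_profiles <- .as_profile_matrix(sigma_profiles, grid)
  stopifnot(nrow(sigma_profiles) >= 2)
  edges <- screen_regulations(sigma_profiles, sigma_profiles, grid, priors,
                              config, r_accept, r_accept_prior, r_trivial,
                              target_kind = "sigma")
  if (!nrow(edges)) return(.empty_edges())
  key <- paste(edges$regulator_id, edges$target_id, sep = "\r")
  rev_key <- paste(edges$target_id, edges$regulator_id, sep = "\r")
  has_reverse <- rev_key %in% key
  rev_trivial <- edges$trivial[match(rev_key, key)]
  edges$mutual <- has_reverse & edges$trivial & !is.na(rev_trivial) &
    rev_trivial
  edges$preferred <- FALSE
  if (!is.null(priors)) {
    fwd_prior <- edges$prior_source != "none"
    bwd_prior <- fwd_prior[match(rev_key, key)]
    bwd_prior[is.na(bwd_prior)] <- FALSE
    edges$preferred <- edges$mutual & fwd_prior & !bwd_prior
  }
  edges
}

#' Export a regulatory network as GEXF
#'
#' Writes a directed GEXF 1.2 graph readable by Gephi: edge weight is the
#' kinetic regulator strength w (arrow thickness in Gephi), with the fit
#' correlation, trivial flag and prior source as edge attributes, and the
#' node kind (and optional expression category) as node attributes.
#'
#' @param edges Edge data frame from [screen_regulations()] or
#'   [sigma_sigma_network()] (accepted edges are written; pass a pre-filtered
#'   frame to override).
#' @param path Output file path.
#' @param node_metadata Optional data frame with columns `id`, `kind` and
#'   optionally `category`; nodes absent from it get kind `"gene"`.
#' @return The path, invisibly.
#' @export
export_network <- function(edges, path, node_metadata = NULL) {
  if (nrow(edges) && "accepted" %in% names(edges))
    edges <- edges[edges$accepted, , drop = FALSE]
  nodes <- unique(c(edges$regulator_id, edges$target_id,
                    node_metadata$id))
  doc <- xml2::xml_new_root("gexf",
    xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "directed",
                               mode = "static")
  nattr <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(nattr, "attribute", id = "kind", title = "kind",
                      type = "string")
  xml2::xml_add_child(nattr, "attribute", id = "category",
                      title = "expression_category", type = "string")
  eattr <- xml2::xml_add_child(graph, "attributes", class = "edge")
  xml2::xml_add_child(eattr, "attribute", id = "correlation",
                      title = "correlation", type = "double")
  xml2::xml_add_child(eattr, "attribute", id = "trivial", title = "trivial",
                      type = "boolean")
  xml2::xml_add_child(eattr, "attribute", id = "prior_source",
                      title = "prior_source", type = "string")
  nodes_el <- xml2::xml_add_child(graph, "nodes")
  for (id in nodes) {
    kind <- "gene"
    category <- ""
    if (!is.null(node_metadata) && id %in% node_metadata$id) {
      row <- node_metadata[match(id, node_metadata$id), ]
      kind <- as.character(row$kind)
      if ("category" %in% names(row)) category <- as.character(row$category)
    } else if (nrow(edges) && id %in% edges$regulator_id &&
               any(edges$target_kind[edges$regulator_id == id] == "sigma")) {
      kind <- "sigma"
    }
    node <- xml2::xml_add_child(nodes_el, "node", id = id, label = id)
    av <- xml2::xml_add_child(node, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "kind", value = kind)
    if (nzchar(category))
      xml2::xml_add_child(av, "attvalue", `for` = "category",
                          value = category)
  }
  edges_el <- xml2::xml_add_child(graph, "edges")
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      e <- xml2::xml_add_child(edges_el, "edge",
        id = sprintf("e%d", i),
        source = edges$regulator_id[i], target = edges$target_id[i],
        weight = format(edges$w[i], digits = 15))
      av <- xml2::xml_add_child(e, "attvalues")
      xml2::xml_add_child(av, "attvalue", `for` = "correlation",
                          value = format(edges$correlation[i], digits = 15))
      xml2::xml_add_child(av, "attvalue", `for` = "trivial",
                          value = tolower(as.character(edges$trivial[i])))
      xml2::xml_add_child(av, "attvalue", `for` = "prior_source",
                          value = as.character(edges$prior_source[i]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read back a GEXF network written by [export_network()]
#'
#' @param path GEXF file path.
#' @return List with `nodes` (id, kind) and `edges` (regulator_id,
#'   target_id, w, correlation, trivial, prior_source) data frames.
#' @export
read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  node_els <- xml2::xml_find_all(doc, ".//g:node", ns)
  nodes <- data.frame(
    id = xml2::xml_attr(node_els, "id"),
    kind = vapply(node_els, function(n) {
      av <- xml2::xml_find_first(
        n, ".//g:attvalue[@for='kind']", ns)
      xml2::xml_attr(av, "value")
    }, character(1)),
    stringsAsFactors = FALSE)
  edge_els <- xml2::xml_find_all(doc, ".//g:edge", ns)
  getav <- function(e, key) {
    av <- xml2::xml_find_first(e,
      sprintf(".//g:attvalue[@for='%s']", key), ns)
    xml2::xml_attr(av, "value")
  }
  edges <- data.frame(
    regulator_id = xml2::xml_attr(edge_els, "source"),
    target_id = xml2::xml_attr(edge_els, "target"),
    w = as.numeric(xml2::xml_attr(edge_els, "weight")),
    correlation = as.numeric(vapply(edge_els, getav, character(1),
                                    "correlation")),
    trivial = vapply(edge_els, getav, character(1), "trivial") == "true",
    prior_source = vapply(edge_els, getav, character(1), "prior_source"),
    stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}
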