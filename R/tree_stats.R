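#' Index of genomic diversity (IGD)
#'
#' For the subclones of one sample type, IGD is the ratio between the summed
#' branch-length distances from their most recent common node to each
#' subclone and the summed distances from the start of the stem (the
#' unmutated root) to the same subclones:
#' `IGD = sum(dS_i) / sum(DS_i)`. It ranges from 0 (all subclones coincide
#' with the common node) to 1 (the common node is the root), and is by
#' construction insensitive to the number of aberrations per sample and the
#' number of samples.
#'
#' @param tree A `clone_tree`.
#' @param taxa Character vector of taxon names (e.g. all subclones detected
#'   in one sample type).
#' @return IGD in `[0, 1]`.
#' @export
igd <- function(tree, taxa) {
  stopifnot(inherits(tree, "clone_tree"))
  taxa <- unique(taxa)
  if (length(taxa) == 0) {
    abort("Empty taxon subset.", class = "clonetrace_validation_error")
  }
  missing_taxa <- setdiff(taxa, tree$taxa$taxon)
  if (length(missing_taxa)) {
    abort(paste0("Taxa not in tree: ", paste(missing_taxa, collapse = ", ")),
          class = "clonetrace_validation_error")
  }
  depths <- node_depths(tree)
  nodes <- tree$taxa$node[match(taxa, tree$taxa$taxon)]
  mrca <- mrca_node(tree, nodes)
  ds <- depths[as.character(nodes)] - depths[as.character(mrca)]
  DS <- depths[as.character(nodes)]
  if (sum(DS) == 0) {
    abort("Subset has zero total root distance; IGD undefined.",
          class = "clonetrace_validation_error")
  }
  sum(ds) / sum(DS)
}

#' Tree irregularity
#'
#' Deviation of the phylogeny from a symmetric star: the sample variance
#' (n - 1 denominator) of the root-to-taxon branch-length distances.
#'
#' @param tree A `clone_tree` with at least two taxa.
#' @return Non-negative variance.
#' @export
irregularity <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  if (nrow(tree$taxa) < 2) {
    abort("Irregularity requires at least two taxa.",
          class = "clonetrace_validation_error")
  }
  depths <- node_depths(tree)
  var(depths[as.character(tree$taxa$node)])
}

#' Total branch length
#'
#' The total number of event acquisitions on the tree (the parsimony score
#' for trees built from conflict-free matrices).
#'
#' @param tree A `clone_tree`.
#' @return Non-negative integer.
#' @export
total_branch_length <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  sum(tree$nodes$length)
}

#' Classify clonal replacement versus linear evolution
#'
#' Compares the lineages dominating at an earlier and a later disease
#' timepoint on the clone phylogeny. The pattern is *linear* when the
#' subclones dominating later descend from a population already detected at
#' the earlier timepoint (an ancestor — or the same subclone — below the
#' patient MRCA was ascertained earlier). It is *collateral clonal
#' replacement* (CCR) when no earlier-detected taxon lies on the root path
#' of any later-dominant subclone below the patient MRCA and the lineages
#' dominating earlier are no longer detected later: the survivors stem from
#' a different most recent ancestor. Mixed evidence yields `"mixed"`.
#'
#' @param tree A `clone_tree`.
#' @param detection Tibble with columns `taxon`, `sample_id`, `timepoint`,
#'   `fraction` (the subclone's own cell fraction in that sample). Use
#'   unrounded fractions: the detection limit, not the reporting grid,
#'   decides what was ascertainable.
#' @param timepoint_order Optional character vector giving the temporal
#'   order; defaults to order of appearance in `detection`.
#' @param detect_threshold Detection limit on the fraction scale (default
#'   0.1, the array detection limit).
#' @return A list of class `replacement_call`: `classification` (`"CCR"`,
#'   `"linear"`, `"mixed"` or `"not_classifiable"`), `dominants`,
#'   and `witnesses` (per later-dominant subclone, the earlier ancestor
#'   found, if any).
#' @export
classify_replacement <- function(tree, detection, timepoint_order = NULL,
                                 detect_threshold = 0.1) {
  stopifnot(inherits(tree, "clone_tree"))
  detection <- as_tibble(detection)
  req <- c("taxon", "sample_id", "timepoint", "fraction")
  if (!all(req %in% names(detection))) {
    abort("`detection` needs columns taxon, sample_id, timepoint, fraction.",
          class = "clonetrace_validation_error")
  }
  tps <- if (is.null(timepoint_order)) unique(detection$timepoint) else {
    intersect(timepoint_order, unique(detection$timepoint))
  }
  if (length(tps) < 2) {
    return(structure(list(classification = "not_classifiable",
                          dominants = NULL, witnesses = NULL),
                     class = "replacement_call"))
  }
  earlier <- tps[1]
  later <- tps[length(tps)]

  # a subclone counts as ascertained at a timepoint when it is replicated
  # (above the limit in >= 2 samples, or all of a single-sample timepoint)
  # or its pooled median across the timepoint's samples clears the limit —
  # one isolated excursion at the detection limit is within measurement
  # error and does not establish presence
  detected_at <- function(tp) {
    d <- detection %>% filter(.data$timepoint == tp)
    n_samp <- dplyr::n_distinct(d$sample_id)
    d %>%
      group_by(.data$taxon) %>%
      summarise(n_over = sum(.data$fraction >= detect_threshold),
                pooled = median(.data$fraction), .groups = "drop") %>%
      filter(.data$n_over >= min(2, n_samp) |
               .data$pooled >= detect_threshold) %>%
      pull("taxon")
  }
  dominant_at <- function(tp) {
    detection %>%
      filter(.data$timepoint == tp) %>%
      group_by(.data$sample_id) %>%
      filter(.data$fraction == max(.data$fraction),
             .data$fraction >= detect_threshold) %>%
      ungroup() %>% pull("taxon") %>% unique()
  }
  det_earlier <- detected_at(earlier)
  det_later <- detected_at(later)
  dom_earlier <- dominant_at(earlier)
  dom_later <- dominant_at(later)

  all_detected <- union(det_earlier, det_later)
  if (!length(all_detected) || !length(dom_later) || !length(dom_earlier)) {
    return(structure(list(classification = "not_classifiable",
                          dominants = NULL, witnesses = NULL),
                     class = "replacement_call"))
  }
  depths <- node_depths(tree)
  tnode <- setNames(tree$taxa$node, tree$taxa$taxon)
  patient_mrca <- mrca_node(tree, tnode[all_detected])

  # the shared trunk — any node that is a proper ancestor of every
  # earlier-dominant lineage — carries no evidence either way. An
  # earlier-dominant that is itself an ancestor of all the others is a
  # remainder population of the trunk and is set aside first.
  earlier_dom_nodes <- unique(tnode[dom_earlier])
  repeat {
    if (length(earlier_dom_nodes) < 2) break
    drop <- vapply(seq_along(earlier_dom_nodes), function(i) {
      all(vapply(earlier_dom_nodes[-i], function(e) {
        earlier_dom_nodes[i] %in% node_path(tree, e)[-1]
      }, logical(1)))
    }, logical(1))
    if (!any(drop)) break
    earlier_dom_nodes <- earlier_dom_nodes[!drop]
  }
  is_trunk <- function(node) {
    all(vapply(earlier_dom_nodes, function(e) {
      e != node && node %in% node_path(tree, e)[-1]
    }, logical(1)))
  }
  dom_later_sub <- dom_later[!vapply(tnode[dom_later], is_trunk, logical(1))]
  if (!length(dom_later_sub)) {
    # a later-dominant that is an earlier-detected ancestor of the earlier
    # dominants is the same lineage regressing to its ancestor: linear
    regressed <- any(vapply(dom_later, function(d) {
      d %in% det_earlier && any(vapply(earlier_dom_nodes, function(e) {
        tnode[[d]] %in% node_path(tree, e)
      }, logical(1)))
    }, logical(1)))
    return(structure(list(
      classification = if (regressed) "linear" else "not_classifiable",
      dominants = list(earlier = dom_earlier, later = dom_later),
      witnesses = NULL), class = "replacement_call"))
  }
  witness <- purrr::map(dom_later_sub, function(d) {
    path <- node_path(tree, tnode[[d]])        # d .. root
    hits <- det_earlier[tnode[det_earlier] %in% path]
    hits[!vapply(tnode[hits], is_trunk, logical(1))]
  })
  names(witness) <- dom_later_sub
  linear_type <- lengths(witness) > 0

  # are the earlier-dominant lineages still detected later?
  parent <- tree_parent_vec(tree)
  descends_from <- function(node, anc) anc %in% node_path(tree, node)
  earlier_persists <- any(vapply(dom_earlier, function(e) {
    any(vapply(det_later, function(l) {
      descends_from(tnode[[l]], tnode[[e]])
    }, logical(1)))
  }, logical(1)))

  classification <- if (all(linear_type)) {
    "linear"
  } else if (!any(linear_type) && !earlier_persists) {
    "CCR"
  } else {
    "mixed"
  }
  structure(list(
    classification = classification,
    dominants = list(earlier = dom_earlier, later = dom_later),
    witnesses = witness,
    earlier_persists = earlier_persists,
    patient_mrca = patient_mrca
  ), class = "replacement_call")
}

#' @export
print.replacement_call <- function(x, ...) {
  cat("<replacement_call> ", x$classification, "\n", sep = "")
  if (!is.null(x$dominants)) {
    cat("  earlier dominants: ",
        paste(x$dominants$earlier, collapse = ", "), "\n",
        "  later dominants:   ",
        paste(x$dominants$later, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
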