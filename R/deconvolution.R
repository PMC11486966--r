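#' Build an event-by-sample MCF matrix
#'
#' @param mcf Long tibble with columns `event`, `sample_id`, `mcf`, or an
#'   already-wide numeric matrix (events in rows).
#' @return Numeric matrix, events in rows, samples in columns; missing
#'   combinations are 0 (an event not detected in a sample has clone
#'   fraction zero there).
#' @export
mcf_matrix <- function(mcf) {
  if (is.matrix(mcf)) {
    storage.mode(mcf) <- "double"
    mcf[is.na(mcf)] <- 0
    return(mcf)
  }
  mcf <- as_tibble(mcf)
  req <- c("event", "sample_id", "mcf")
  if (!all(req %in% names(mcf))) {
    abort("Long MCF input needs columns event, sample_id, mcf.",
          class = "clonetrace_validation_error")
  }
  wide <- mcf %>%
    select(all_of(req)) %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "mcf",
                       values_fill = 0, values_fn = mean)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$event
  m[is.na(m)] <- 0
  m
}

#' Group events with similar MCF patterns across samples
#'
#' Events whose mutated clone fractions differ by at most `tol` in every
#' sample are merged into one group (complete linkage under the per-sample
#' Chebyshev metric, so no group spans more than `tol` internally and the
#' result does not depend on input order). The group profile is the
#' per-sample mean over members, rounded to the nearest 0.1 — the final
#' clone size of all events in the group.
#'
#' @param mcf Long tibble or event-by-sample matrix, see [mcf_matrix()].
#' @param tol Pattern tolerance (default 0.15, covering the ~10% clone-size
#'   error margin of array data plus rounding).
#' @return An object of class `event_groups`: membership tibble, rounded
#'   profile matrix (`profile`), and unrounded per-sample means
#'   (`profile_raw`).
#' @export
group_events <- function(mcf, tol = 0.15) {
  if (tol < 0) abort("`tol` must be >= 0.", class = "clonetrace_config_error")
  m <- mcf_matrix(mcf)
  if (nrow(m) == 0) {
    abort("Empty MCF matrix.", class = "clonetrace_validation_error")
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("e", seq_len(nrow(m)))
  if (nrow(m) == 1) {
    cl <- 1L
  } else {
    cheb <- as.dist(outer(seq_len(nrow(m)), seq_len(nrow(m)),
                          Vectorize(function(i, j) max(abs(m[i, ] - m[j, ])))))
    hc <- hclust(cheb, method = "complete")
    cl <- cutree(hc, h = tol + 1e-9)
  }
  # clusters whose rounded profiles coincide share a final clone size in
  # every sample and therefore describe the same subclone: merge them
  first_raw <- do.call(rbind, lapply(split(seq_len(nrow(m)), cl), function(idx) {
    colMeans(m[idx, , drop = FALSE])
  }))
  sig <- apply(round_to(pmin(pmax(first_raw, 0), 1), 0.1), 1,
               paste, collapse = ",")
  cl <- match(sig, unique(sig))[match(as.character(cl), rownames(first_raw))]
  raw <- do.call(rbind, lapply(split(seq_len(nrow(m)), cl), function(idx) {
    colMeans(m[idx, , drop = FALSE])
  }))
  # order groups by descending total fraction; stable on ties
  ord <- order(-rowSums(raw), rownames(raw))
  raw <- raw[ord, , drop = FALSE]
  ids <- paste0("G", seq_len(nrow(raw)))
  members <- split(rownames(m), cl)[rownames(raw)]
  rownames(raw) <- ids
  prof <- round_to(pmin(pmax(raw, 0), 1), 0.1)
  membership <- tibble(
    group = rep(ids, lengths(members)),
    event = unlist(members, use.names = FALSE)
  )
  structure(list(
    groups = membership,
    profile = prof,
    profile_raw = raw,
    mcf = m,
    samples = colnames(m),
    tol = tol
  ), class = "event_groups")
}

#' @export
print.event_groups <- function(x, ...) {
  cat("<event_groups> ", nrow(x$profile), " groups / ",
      nrow(x$groups), " events / ", length(x$samples), " samples\n", sep = "")
  print(round(x$profile, 2))
  invisible(x)
}

#' @export
tidy.event_groups <- function(x, ...) {
  prof <- as_tibble(x$profile, rownames = "group") %>%
    tidyr::pivot_longer(-"group", names_to = "sample_id",
                        values_to = "fraction")
  left_join(x$groups, prof, by = "group", relationship = "many-to-many")
}

# map an event-level pair list to group-level barred pairs
no_nest_groups <- function(groups, no_nest) {
  if (is.null(no_nest) || nrow(as_tibble(no_nest)) == 0) {
    return(tibble(g1 = character(), g2 = character()))
  }
  nn <- as_tibble(no_nest)
  lookup <- setNames(groups$groups$group, groups$groups$event)
  g1 <- unname(lookup[as.character(nn[[1]])])
  g2 <- unname(lookup[as.character(nn[[2]])])
  keep <- !is.na(g1) & !is.na(g2)
  nn <- tibble(g1 = g1[keep], g2 = g2[keep])
  if (any(nn$g1 == nn$g2)) {
    abort(paste0("Events barred from nesting fell into the same group: ",
                 paste(unique(nn$g1[nn$g1 == nn$g2]), collapse = ", "),
                 ". Lower `tol` or review the event calls."),
          class = "clonetrace_constraint_conflict")
  }
  nn
}

#' Resolve nesting and parallel relations among event groups
#'
#' Deduces the subclone configuration across biopsies from the grouped clone
#' sizes: a group nests inside another only when its fraction is contained
#' (within `tol`) in every sample; two groups whose fractions sum above 100%
#' in some sample must be nested (pigeonhole); pairs barred by the `no_nest`
#' matrix (same segment, different allelic composition — "mixed") are never
#' nested. Each group is attached to its deepest feasible container, which
#' maximizes nesting consistency while keeping every antichain of parallel
#' subclones within 100% per biopsy.
#'
#' @param groups An `event_groups` object.
#' @param no_nest Optional two-column data frame of event pairs that must
#'   not be nested into each other.
#' @param tol Containment tolerance on the rounded profiles (default 0.1,
#'   the clone-size rounding grid).
#' @param sigma_event Per-event, per-sample clone-size noise used by the
#'   indistinguishability merge. `NULL` (default) estimates it from the
#'   within-group residuals; pipelines with clonal reference segments pass
#'   a calibration measured on those.
#' @return An object of class `subclone_config` with a `nodes` tibble
#'   (`subclone`, `parent` — `NA` for children of the unmutated root —,
#'   `annotation`), the group profiles, and per-sample own fractions
#'   (profile minus the profiles of nested children).
#' @export
resolve_configuration <- function(groups, no_nest = NULL, tol = 0.1,
                                  sigma_event = NULL) {
  stopifnot(inherits(groups, "event_groups"))
  barred <- no_nest_groups(groups, no_nest)

  # among feasible configurations, prefer the one with fewest subclones:
  # two groups whose profiles cannot be told apart at the reporting
  # tolerance plus three standard errors (noise estimated from the
  # within-group residuals) describe the same subclone and are merged
  prof <- groups$profile
  raw <- groups$profile_raw
  members <- split(groups$groups$event, groups$groups$group)[rownames(prof)]
  wt <- lengths(members)
  # per-event noise from within-group residuals; only groups with >= 2
  # members are informative, and their residuals understate the noise by
  # sqrt((n - 1) / n)
  if (is.null(sigma_event)) {
    ev_group <- groups$groups$group[match(rownames(groups$mcf),
                                          groups$groups$event)]
    grp_n <- table(ev_group)
    multi <- names(grp_n)[grp_n >= 2]
    if (length(multi)) {
      idx <- ev_group %in% multi
      resid <- (groups$mcf[idx, , drop = FALSE] -
                  groups$profile_raw[ev_group[idx], , drop = FALSE]) *
        sqrt(as.numeric(grp_n[ev_group[idx]]) /
               (as.numeric(grp_n[ev_group[idx]]) - 1))
      sigma_event <- stats::mad(resid, center = 0)
    } else {
      sigma_event <- 0
    }
  }
  pair_barred <- function(a, b) {
    any((barred$g1 == a & barred$g2 == b) | (barred$g1 == b & barred$g2 == a))
  }
  repeat {
    nG <- nrow(prof)
    if (nG < 2) break
    best <- NULL
    best_d <- Inf
    for (i in seq_len(nG - 1)) for (j in (i + 1):nG) {
      se <- sigma_event * sqrt(1 / wt[i] + 1 / wt[j])
      if (all(abs(raw[i, ] - raw[j, ]) <= tol + 3 * se + 1e-9) &&
          !pair_barred(rownames(prof)[i], rownames(prof)[j])) {
        d <- max(abs(raw[i, ] - raw[j, ])) / max(se, 1e-6)
        if (d < best_d) {
          best <- c(i, j)
          best_d <- d
        }
      }
    }
    if (is.null(best)) break
    i <- best[1]; j <- best[2]
    raw[i, ] <- (wt[i] * raw[i, ] + wt[j] * raw[j, ]) / (wt[i] + wt[j])
    prof[i, ] <- round_to(pmin(pmax(raw[i, ], 0), 1), 0.1)
    members[[i]] <- c(members[[i]], members[[j]])
    wt[i] <- wt[i] + wt[j]
    # barred relations of the absorbed group transfer to the merged one
    absorbed <- rownames(prof)[j]
    keepnm <- rownames(prof)[i]
    barred$g1[barred$g1 == absorbed] <- keepnm
    barred$g2[barred$g2 == absorbed] <- keepnm
    raw <- raw[-j, , drop = FALSE]
    prof <- prof[-j, , drop = FALSE]
    members <- members[-j]
    wt <- wt[-j]
  }
  membership <- tibble(
    subclone = rep(names(members), lengths(members)),
    event = unlist(members, use.names = FALSE)
  )

  g <- rownames(prof)
  nG <- length(g)
  is_barred <- pair_barred
  eps <- 1e-9
  contained <- function(a, b) all(prof[a, ] <= prof[b, ] + tol + eps)
  # pigeonhole forcing is tested on the unrounded fractions: rounding two
  # fractions upward must not fabricate an impossibility
  forced <- function(a, b) any(raw[a, ] + raw[b, ] > 1 + tol + eps)
  # repair direction must be supported by containment at twice the
  # tolerance, otherwise the excess is a measurement violation, not
  # evidence of co-occurrence
  contained_loose <- function(a, b) all(prof[a, ] <= prof[b, ] + 2 * tol + eps)

  ord <- order(-rowSums(prof), g)
  parent <- setNames(rep(NA_character_, nG), g)
  for (k in seq_along(ord)) {
    gi <- g[ord[k]]
    if (k == 1) next
    placed <- g[ord[seq_len(k - 1)]]
    cand <- placed[vapply(placed, function(p) {
      !is_barred(gi, p) && contained(gi, p)
    }, logical(1))]
    if (length(cand)) {
      # deepest feasible container = smallest total fraction among candidates
      tot <- rowSums(prof[cand, , drop = FALSE])
      parent[gi] <- cand[order(tot, cand)][1]
    }
  }
  anc <- function(x) {
    out <- character()
    while (!is.na(parent[x])) {
      x <- parent[x]
      out <- c(out, x)
    }
    out
  }
  # pigeonhole: forced pairs must end up in an ancestor relation; repair by
  # re-attaching the smaller group under the larger one when they did not
  desc_of <- function(x) g[vapply(g, function(y) x %in% anc(y), logical(1))]
  violations <- character()
  for (iter in 1:3) {
    changed <- FALSE
    for (a in g) for (b in g) {
      if (a < b && forced(a, b)) {
        if (is_barred(a, b)) {
          abort(paste0("Groups ", a, " and ", b, " exceed 100% together in ",
                       "a sample but are barred from nesting."),
                class = "clonetrace_constraint_conflict")
        }
        if (!(a %in% anc(b) || b %in% anc(a))) {
          big <- if (sum(prof[a, ]) >= sum(prof[b, ])) a else b
          small <- setdiff(c(a, b), big)
          if (contained_loose(small, big) && !(big %in% desc_of(small))) {
            parent[small] <- big
            changed <- TRUE
          } else {
            s <- which(raw[a, ] + raw[b, ] > 1 + tol + eps)[1]
            violations <- c(violations, paste0(
              "parallel groups ", a, " and ", b, " sum to ",
              round(raw[a, s] + raw[b, s], 2), " in sample ",
              colnames(prof)[s]))
          }
        }
      }
    }
    if (!changed) break
  }
  children <- split(g[!is.na(parent)], parent[!is.na(parent)])
  own <- prof
  own_raw <- raw
  for (p in names(children)) {
    kid_sum <- colSums(prof[children[[p]], , drop = FALSE])
    own[p, ] <- pmax(prof[p, ] - kid_sum, 0)
    # child fractions below zero are noise; subtracting them unclamped
    # would inflate the parent's residual population
    own_raw[p, ] <- raw[p, ] -
      colSums(pmax(raw[children[[p]], , drop = FALSE], 0))
  }
  # antichain check: siblings (incl. top level) must fit inside their parent
  sibsets <- c(children, list(`(root)` = g[is.na(parent)]))
  for (p in names(sibsets)) {
    cap <- if (p == "(root)") rep(1, ncol(prof)) else pmin(prof[p, ], 1)
    tot <- colSums(prof[sibsets[[p]], , drop = FALSE])
    bad <- which(tot > cap + tol + eps)
    if (length(bad)) {
      violations <- c(violations, paste0(
        "parallel subclones under ", p, " sum to ", round(tot[bad[1]], 2),
        " in sample ", colnames(prof)[bad[1]]))
    }
  }
  if (length(violations)) {
    warn(paste0("Configuration constraint violations:\n  ",
                paste(violations, collapse = "\n  ")))
  }
  nodes <- tibble(
    subclone = g,
    parent = unname(parent[g]),
    annotation = "observed"
  ) %>% arrange(match(.data$subclone, g[ord]))
  structure(list(
    nodes = nodes,
    profile = prof,
    profile_raw = raw,
    own = own,
    own_raw = own_raw,
    membership = membership,
    groups = groups,
    samples = groups$samples,
    tol = tol,
    violations = violations
  ), class = "subclone_config")
}

#' @export
print.subclone_config <- function(x, ...) {
  cat("<subclone_config> ", nrow(x$nodes), " subclones / ",
      length(x$samples), " samples\n", sep = "")
  print(x$nodes, n = Inf)
  invisible(x)
}

#' @export
tidy.subclone_config <- function(x, ...) {
  own <- as_tibble(x$own, rownames = "subclone") %>%
    tidyr::pivot_longer(-"subclone", names_to = "sample_id",
                        values_to = "fraction")
  left_join(own, x$nodes, by = "subclone")
}

#' Add inferred stem / inferred private events to a configuration
#'
#' Reconciles event calls that cannot be placed in a single phylogenetic
#' order: (i) gains with identical breakpoints but different allele counts
#' across samples — the gain with the lowest allele count is inferred as
#' stem, its profile extended to cover the higher-count states; (ii)
#' whole-chromosome events whose clone-size patterns cross other events
#' while the pigeonhole forces co-occurrence — irreconcilable with one
#' order, so they are split into per-sample inferred-private copies
#' (parallel events). Consistent configurations are returned unchanged.
#'
#' @param config A `subclone_config`.
#' @param events_meta Event metadata tibble: `event`, `chrom`, `start`,
#'   `end`, `class` (`gain`/`loss`/`cnni`/`snv`), `n_a`, `n_b`, and logical
#'   `whole_chrom`.
#' @param no_nest Barred pairs forwarded to the re-resolution.
#' @return A re-resolved `subclone_config`; inferred events carry
#'   `inferred_stem` / `inferred_private` in the `annotations` element.
#' @export
infer_missing_events <- function(config, events_meta, no_nest = NULL) {
  stopifnot(inherits(config, "subclone_config"))
  meta <- as_tibble(events_meta)
  m <- config$groups$mcf
  tol <- config$tol
  annot <- tibble(event = character(), annotation = character())
  eps <- 1e-9

  # (i) same-breakpoint gains with different allele counts
  gains <- meta %>%
    filter(.data$class == "gain", .data$event %in% rownames(m)) %>%
    mutate(locus = paste(.data$chrom, .data$start, .data$end, sep = ":"),
           total = .data$n_a + .data$n_b)
  for (loc in unique(gains$locus)) {
    set <- gains %>% filter(.data$locus == loc) %>% arrange(.data$total)
    if (nrow(set) > 1 && length(unique(set$total)) > 1) {
      low <- set$event[1]
      cover <- apply(m[set$event, , drop = FALSE], 2, max)
      m[low, ] <- cover
      annot <- bind_rows(annot, tibble(event = low,
                                       annotation = "inferred_stem"))
    }
  }

  # (ii) whole-chromosome events irreconcilable with a single order
  if (!"whole_chrom" %in% names(meta)) meta$whole_chrom <- FALSE
  wch <- intersect(meta$event[meta$whole_chrom], rownames(m))
  for (e in wch) {
    others <- setdiff(rownames(m), e)
    clash <- vapply(others, function(o) {
      cross <- any(m[e, ] > m[o, ] + tol + eps) &&
        any(m[o, ] > m[e, ] + tol + eps)
      forced <- any(m[e, ] + m[o, ] > 1 + eps)
      cross && forced
    }, logical(1))
    if (any(clash)) {
      present <- which(m[e, ] > 0)
      pieces <- matrix(0, nrow = length(present), ncol = ncol(m),
                       dimnames = list(paste0(e, "@", colnames(m)[present]),
                                       colnames(m)))
      for (i in seq_along(present)) pieces[i, present[i]] <- m[e, present[i]]
      m <- rbind(m[setdiff(rownames(m), e), , drop = FALSE], pieces)
      annot <- bind_rows(annot, tibble(event = rownames(pieces),
                                       annotation = "inferred_private"))
    }
  }

  out <- resolve_configuration(group_events(m, tol = config$groups$tol),
                               no_nest = no_nest, tol = tol)
  out$annotations <- annot
  out
}

#' Deconvolve SNP-array data from xenograft or cell-line samples
#'
#' Pure-tumor rule set (tumor fraction 1, reference ploidy 2): aberrations
#' with MCF at or above 0.9 are clonal (set to 1); final clone sizes are
#' rounded to the nearest 10%; the sum of parallel subclones may reach 120%
#' (two concomitant subclones carry a 20% error margin) and is renormalized
#' to 100% when above it; a 2+0 copy-number-neutral imbalance in a sample
#' whose sibling samples mostly carry the 1+2 trisomy at the same locus is
#' ordered as an allele loss from the trisomy; an aberration unique to one
#' lineage (cell line) or tumor (PDX pair) is private, all others shared or
#' stem.
#'
#' @param segments Quantified segment table (see [quantify_segments()]) with
#'   an `event` identifier column; MSF equals MCF at purity 1.
#' @param lineage Named character vector mapping `sample_id` to lineage /
#'   tumor; defaults to each sample being its own lineage.
#' @param tol Grouping tolerance passed to [group_events()].
#' @return A list: `config` (`subclone_config`), `sizes` (rounded clone-size
#'   matrix after normalization), `events` (annotation tibble with
#'   clonal/private calls), `cnni_from_trisomy` (events re-ordered under the
#'   trisomy rule).
#' @export
pdx_deconvolve <- function(segments, lineage = NULL, tol = 0.15) {
  segments <- as_tibble(segments)
  if (!"event" %in% names(segments)) {
    abort("`segments` needs an `event` identifier column.",
          class = "clonetrace_validation_error")
  }
  if (!"msf" %in% names(segments)) {
    segments <- quantify_segments(segments)
  }
  segments$mcf <- pmin(pmax(segments$msf, 0), 1.2)
  segments$mcf[segments$mcf >= 0.9] <- 1       # clonal call
  segments$mcf <- pmin(segments$mcf, 1)

  m <- mcf_matrix(segments %>% select("event", "sample_id", "mcf"))

  # CNNI 2+0 against a majority-trisomy background: order as loss from 1+2
  cnni_reordered <- character()
  key <- segments %>%
    distinct(.data$event, .data$chrom, .data$start, .data$end,
             .data$n_a, .data$n_b)
  loci <- key %>% mutate(locus = paste(.data$chrom, .data$start, .data$end,
                                       sep = ":"))
  for (loc in unique(loci$locus)) {
    set <- loci %>% filter(.data$locus == loc)
    cn <- set %>% filter(.data$n_a == 0 | .data$n_b == 0,
                         .data$n_a + .data$n_b == 2)
    tri <- set %>% filter(pmin(.data$n_a, .data$n_b) == 1,
                          pmax(.data$n_a, .data$n_b) == 2)
    if (nrow(cn) == 1 && nrow(tri) == 1) {
      cn_samples <- colnames(m)[m[cn$event, ] > 0]
      tri_samples <- colnames(m)[m[tri$event, ] > 0]
      other <- setdiff(colnames(m), cn_samples)
      if (length(other) > 0 &&
          length(intersect(other, tri_samples)) > length(other) / 2) {
        # the trisomy is ancestral: extend it over the CNNI samples
        m[tri$event, ] <- pmax(m[tri$event, ], m[cn$event, ])
        cnni_reordered <- c(cnni_reordered, cn$event)
      }
    }
  }

  groups <- group_events(m, tol = tol)
  config <- resolve_configuration(groups, tol = 0.1)

  # per-sample normalization of clone sizes when the total exceeds 100%
  sizes <- config$own
  tot <- colSums(sizes)
  over_cap <- tot > 1.2 + 1e-9
  if (any(over_cap)) {
    abort(paste0("Parallel subclones exceed the 120% margin in sample(s): ",
                 paste(colnames(sizes)[over_cap], collapse = ", ")),
          class = "clonetrace_constraint_conflict")
  }
  for (s in which(tot > 1 + 1e-9)) sizes[, s] <- sizes[, s] / tot[s]

  if (is.null(lineage)) {
    lineage <- setNames(colnames(m), colnames(m))
  }
  ev_annot <- tibble(event = rownames(m)) %>%
    mutate(
      carriers = map(.data$event, ~ colnames(m)[m[.x, ] > 0]),
      n_lineages = map_int(.data$carriers,
                           ~ length(unique(lineage[.x]))),
      status = ifelse(.data$n_lineages <= 1, "private", "shared_or_stem"),
      clonal = map_lgl(.data$event, ~ all(m[.x, m[.x, ] > 0] >= 1))
    ) %>%
    select("event", "status", "clonal")

  list(config = config, sizes = sizes, events = ev_annot,
       cnni_from_trisomy = cnni_reordered)
}

#' Event matrix and subclone fractions from a configuration
#'
#' Expands a resolved configuration into the binary subclone-by-event matrix
#' used for phylogeny construction: each subclone row carries every event
#' acquired along its root path. Per-sample subclone fractions (own
#' fractions, not cumulated over descendants) accompany the matrix.
#'
#' @param config A `subclone_config`.
#' @return List with `matrix` (binary, subclones x events) and `fractions`
#'   (tibble `subclone`, `sample_id`, `fraction`).
#' @export
event_matrix <- function(config) {
  stopifnot(inherits(config, "subclone_config"))
  membership <- split(config$membership$event, config$membership$subclone)
  g <- config$nodes$subclone
  parent <- setNames(config$nodes$parent, g)
  events <- unique(config$membership$event)
  m <- matrix(0L, nrow = length(g), ncol = length(events),
              dimnames = list(g, events))
  for (s in g) {
    x <- s
    path_events <- character()
    repeat {
      path_events <- c(path_events, membership[[x]])
      if (is.na(parent[[x]])) break
      x <- parent[[x]]
    }
    m[s, path_events] <- 1L
  }
  fractions <- as_tibble(config$own, rownames = "subclone") %>%
    tidyr::pivot_longer(-"subclone", names_to = "sample_id",
                        values_to = "fraction")
  list(matrix = m, fractions = fractions)
}
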