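# Divergence state: symmetric non-negative integer matrix of pairwise
# genetic-incompatibility distance between a species' demes (the finest
# persistent population groups; each deme lies within one dispersal
# cluster). The zero diagonal is maintained throughout.

#' Update pairwise genetic incompatibility
#'
#' Demes in different dispersal clusters drift apart (+1 per time step);
#' demes sharing a cluster converge (-1 per step, floored at zero).
#'
#' @param state symmetric non-negative integer matrix of pairwise divergence.
#' @param membership cluster id for each deme (row of `state`).
#' @return updated divergence matrix.
#' @export
update_divergence <- function(state, membership) {
  k <- nrow(state)
  if (k <= 1) return(state)
  same <- outer(membership, membership, `==`)
  state <- state + 1L - 2L * same
  state[state < 0L] <- 0L
  diag(state) <- 0L
  state
}

#' Split a species at the incompatibility threshold
#'
#' Builds a graph on demes with edges wherever divergence is still below the
#' speciation threshold; its connected components are the daughter species.
#' One component (by convention the most abundant) keeps the ancestral
#' identity.
#'
#' @param state divergence matrix.
#' @param s_threshold speciation threshold `s` (divergence "reaching" the
#'   threshold, i.e. `>= s`, separates demes).
#' @return integer vector: component id (1-based) per deme; a single
#'   component means no speciation.
#' @export
speciate <- function(state, s_threshold) {
  k <- nrow(state)
  if (k <= 1) return(rep(1L, k))
  below <- state < s_threshold
  pairs <- which(below & upper.tri(below), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  if (nrow(pairs) > 0) g <- igraph::add_edges(g, t(pairs))
  as.integer(igraph::components(g)$membership)
}

#' Merge demes that have re-homogenized
#'
#' When demes fuse (same cluster, divergence decayed to zero) their rows are
#' collapsed; the merged deme's divergence to every outsider is the
#' abundance-weighted mean of its parts' divergences, rounded to the
#' nearest integer.
#'
#' @param state divergence matrix.
#' @param groups integer vector mapping each deme to its merged group.
#' @param weights abundance weight per deme.
#' @return divergence matrix over the merged groups (in order of first
#'   appearance of each group).
#' @export
merge_divergence <- function(state, groups, weights) {
  ug <- unique(groups)
  if (length(ug) == nrow(state)) return(state)
  k <- length(ug)
  out <- matrix(0L, k, k)
  for (a in seq_len(k - 1)) {
    ia <- which(groups == ug[a])
    for (b in (a + 1):k) {
      ib <- which(groups == ug[b])
      w <- outer(weights[ia], weights[ib])
      if (sum(w) <= 0) w[] <- 1
      v <- as.integer(round(sum(state[ia, ib, drop = FALSE] * w) / sum(w)))
      out[a, b] <- v
      out[b, a] <- v
    }
  }
  out
}

#' Duplicate deme rows when a deme is split across clusters
#'
#' Each part inherits the parent's divergence row; parts of the same former
#' deme start at zero mutual divergence.
#'
#' @param state divergence matrix.
#' @param parents integer vector: for each new deme, the row of `state` it
#'   descends from.
#' @return expanded divergence matrix.
#' @export
split_divergence <- function(state, parents) {
  out <- state[parents, parents, drop = FALSE]
  same <- outer(parents, parents, `==`)
  out[same] <- 0L
  out
}

# ---- phylogeny --------------------------------------------------------------

#' Create a lineage table
#'
#' @param founders lineage ids of the founding species.
#' @param step birth time step of the founders.
#' @return tibble with columns `lineage`, `parent` (NA for founders),
#'   `birth_step`, `death_step` (NA while extant).
#' @export
new_phylogeny <- function(founders, step = 1L) {
  tibble::tibble(
    lineage = as.integer(founders),
    parent = NA_integer_,
    birth_step = as.integer(step),
    death_step = NA_integer_
  )
}

#' Record a speciation event in the lineage table
#'
#' @param phylogeny lineage tibble.
#' @param lineage new lineage id.
#' @param parent parent lineage id.
#' @param step birth time step.
#' @export
record_speciation <- function(phylogeny, lineage, parent, step) {
  dplyr::bind_rows(phylogeny, tibble::tibble(
    lineage = as.integer(lineage), parent = as.integer(parent),
    birth_step = as.integer(step), death_step = NA_integer_
  ))
}

#' Record an extinction in the lineage table
#'
#' @param phylogeny lineage tibble.
#' @param lineage lineage id going extinct.
#' @param step death time step.
#' @export
record_extinction <- function(phylogeny, lineage, step) {
  phylogeny$death_step[phylogeny$lineage == lineage] <- as.integer(step)
  phylogeny
}

phylo_end_step <- function(phylogeny, final_step) {
  ifelse(is.na(phylogeny$death_step), final_step, phylogeny$death_step)
}

#' Total branch length of the lineage table
#'
#' Sum of all lineage lifespans (birth to death or to the final step), in
#' Myr.
#'
#' @param phylogeny lineage tibble.
#' @param final_step last simulated step (caps extant lineages).
#' @param step_myr duration of one step in Myr (default 0.01).
#' @export
phylo_total_length <- function(phylogeny, final_step, step_myr = 0.01) {
  sum(phylo_end_step(phylogeny, final_step) - phylogeny$birth_step) * step_myr
}

prune_extinct <- function(phylogeny) {
  keep <- logical(nrow(phylogeny))
  extant <- is.na(phylogeny$death_step)
  keep[extant] <- TRUE
  repeat {
    parents <- phylogeny$parent[keep]
    add <- !keep & phylogeny$lineage %in% parents
    if (!any(add)) break
    keep[add] <- TRUE
  }
  phylogeny[keep, , drop = FALSE]
}

#' Export the phylogeny as a Newick string
#'
#' Writes the lineage table as a rooted Newick tree with branch lengths in
#' Myr. The ancestral identity persists through splits, so each speciation
#' appears as an internal node whose one child continues the parent lineage.
#' Multiple founders are attached to an artificial zero-age root.
#'
#' @param phylogeny lineage tibble.
#' @param final_step last simulated step.
#' @param extant_only drop lineages without extant descendants (for
#'   phylogenetic-diversity computations on the living assemblage).
#' @param step_myr duration of one step in Myr.
#' @return a single Newick string, tips labelled `sp<lineage>`.
#' @export
to_newick <- function(phylogeny, final_step, extant_only = FALSE,
                      step_myr = 0.01) {
  if (nrow(phylogeny) == 0) stop("empty phylogeny", call. = FALSE)
  ph <- if (extant_only) prune_extinct(phylogeny) else phylogeny
  if (nrow(ph) == 0) stop("no extant lineages to export", call. = FALSE)
  ends <- phylo_end_step(ph, final_step)

  extant <- is.na(ph$death_step)

  # returns list(label = subtree string without its own branch length,
  # len = branch length in steps), or NULL for a pruned dead tail
  build <- function(lin, from_step) {
    i <- which(ph$lineage == lin)
    kids <- ph[!is.na(ph$parent) & ph$parent == lin &
                 ph$birth_step > from_step, , drop = FALSE]
    kids <- kids[order(kids$birth_step), , drop = FALSE]
    if (nrow(kids) == 0) {
      if (extant_only && !extant[i]) return(NULL)
      return(list(label = sprintf("sp%d", lin), len = ends[i] - from_step))
    }
    b <- kids$birth_step[1]
    sibs <- kids$lineage[kids$birth_step == b]  # polytomy on a multi-way split
    children <- c(list(build(lin, b)), lapply(sibs, build, from_step = b))
    children <- children[!vapply(children, is.null, logical(1))]
    if (length(children) == 0) return(NULL)
    if (length(children) == 1) {  # suppress the unary node left by pruning
      child <- children[[1]]
      return(list(label = child$label, len = child$len + (b - from_step)))
    }
    lab <- paste(vapply(children, function(ch) {
      sprintf("%s:%g", ch$label, ch$len * step_myr)
    }, character(1)), collapse = ",")
    list(label = sprintf("(%s)", lab), len = b - from_step)
  }

  founders <- ph[is.na(ph$parent) | !(ph$parent %in% ph$lineage), , drop = FALSE]
  parts <- vapply(seq_len(nrow(founders)), function(i) {
    node <- build(founders$lineage[i], founders$birth_step[i])
    sprintf("%s:%g", node$label, node$len * step_myr)
  }, character(1))
  if (length(parts) == 1) paste0("(", parts, ");") else
    paste0("(", paste(parts, collapse = ","), "):0;")
}
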