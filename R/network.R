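# Haplotype networks: minimum spanning network with inferred intermediate
# nodes (the "missing haplotype" filled circles of classic network figures).

#' Build a haplotype network from an alignment
#'
#' Identical sequences are collapsed into haplotype nodes carrying their
#' multiplicity and basin composition. The network is the minimum spanning
#' network on pairwise substitution counts: every edge that participates
#' in at least one minimum spanning tree is retained, so equal-weight
#' alternative connections survive. An edge of k substitution steps is
#' expanded into k unit-step edges through k-1 inferred (unobserved)
#' haplotype nodes.
#'
#' @param aln An `aligned_sequences` tibble; if it carries a `basin`
#'   column (see [join_metadata()]) basin composition is recorded.
#' @param partition Optional `mitotype_partition`; node mitotype labels
#'   are the (majority) label of their members.
#' @return A `haplotype_network`: list with `graph` (an igraph with unit
#'   edges and logical vertex attribute `inferred`), `haplotypes` (tibble
#'   of observed nodes) and `edges` (tibble of collapsed-haplotype edges
#'   with step counts).
#' @export
build_network <- function(aln, partition = NULL) {
  key <- aln$residues
  groups <- split(seq_len(nrow(aln)), key)
  mult <- lengths(groups)
  first_id <- vapply(groups, function(i) min(aln$specimen[i]), character(1))
  ord <- order(-mult, first_id)
  groups <- groups[ord]
  hap_ids <- paste0("H", seq_along(groups))

  members <- purrr::map(groups, ~ aln$specimen[.x])
  basins <- if ("basin" %in% names(aln)) {
    vapply(groups, function(i) {
      tb <- table(aln$basin[i])
      paste(paste0(names(tb), ":", tb), collapse = ",")
    }, character(1))
  } else rep(NA_character_, length(groups))
  mito <- if (!is.null(partition)) {
    map <- setNames(partition$mitotype, partition$specimen)
    vapply(members, function(m) {
      tb <- sort(table(map[m]), decreasing = TRUE)
      if (length(tb) == 0) NA_character_ else names(tb)[1]
    }, character(1))
  } else rep(NA_character_, length(groups))

  haps <- tibble::tibble(
    haplotype = hap_ids,
    multiplicity = unname(mult[ord]),
    representative = unname(first_id[ord]),
    members = members,
    basins = unname(basins),
    mitotype = unname(mito)
  )

  hap_aln <- structure(
    tibble::tibble(specimen = hap_ids, marker = aln$marker[1],
                   residues = names(groups)),
    class = class(aln))
  n <- nrow(haps)
  if (n == 1) {
    g <- igraph::make_empty_graph(directed = FALSE)
    g <- igraph::add_vertices(g, 1, name = hap_ids,
                              inferred = FALSE,
                              multiplicity = haps$multiplicity)
    return(structure(list(graph = g, haplotypes = haps,
                          edges = tibble::tibble(from = character(),
                                                 to = character(),
                                                 steps = integer())),
                     class = "haplotype_network"))
  }
  dmat <- substitution_counts(hap_aln)$d[hap_ids, hap_ids]
  dmat[is.na(dmat)] <- Inf
  edges <- msn_edges(dmat)
  edges$from <- hap_ids[edges$i]
  edges$to <- hap_ids[edges$j]

  # Expand k-step edges through k-1 inferred intermediate nodes.
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, n, name = hap_ids, inferred = FALSE,
                            multiplicity = haps$multiplicity)
  inf_counter <- 0
  for (r in seq_len(nrow(edges))) {
    k <- edges$steps[r]
    chain <- edges$from[r]
    if (k > 1) {
      mids <- paste0("x", inf_counter + seq_len(k - 1))
      inf_counter <- inf_counter + k - 1
      g <- igraph::add_vertices(g, k - 1, name = mids, inferred = TRUE,
                                multiplicity = 0)
      chain <- c(chain, mids)
    }
    chain <- c(chain, edges$to[r])
    g <- igraph::add_edges(g, as.vector(rbind(chain[-length(chain)],
                                              chain[-1])))
  }
  structure(list(graph = g, haplotypes = haps,
                 edges = tibble::as_tibble(edges[c("from", "to", "steps")])),
            class = "haplotype_network")
}

# All edges belonging to at least one minimum spanning tree: Kruskal over
# ascending weight classes, testing every edge of a class against the
# components formed by strictly smaller weights (cycle property).
msn_edges <- function(dmat) {
  n <- nrow(dmat)
  ut <- which(upper.tri(dmat), arr.ind = TRUE)
  w <- dmat[ut]
  keep_i <- integer(); keep_j <- integer(); keep_w <- numeric()
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (wc in sort(unique(w[is.finite(w)]))) {
    idx <- which(w == wc)
    sel <- idx[vapply(idx, function(e) {
      find(ut[e, 1]) != find(ut[e, 2])
    }, logical(1))]
    keep_i <- c(keep_i, ut[sel, 1]); keep_j <- c(keep_j, ut[sel, 2])
    keep_w <- c(keep_w, w[sel])
    for (e in sel) {
      ra <- find(ut[e, 1]); rb <- find(ut[e, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  data.frame(i = keep_i, j = keep_j, steps = as.integer(keep_w))
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("<haplotype_network> ", nrow(x$haplotypes), " haplotypes, ",
      nrow(x$edges), " collapsed edges, ",
      sum(igraph::V(x$graph)$inferred), " inferred intermediates\n",
      sep = "")
  invisible(x)
}

#' Write a haplotype network as GraphML plus an edge-list TSV
#'
#' @param net A `haplotype_network`.
#' @param graphml,edgelist Output paths (either may be `NULL` to skip).
#' @return `net`, invisibly.
#' @export
write_network <- function(net, graphml = NULL, edgelist = NULL) {
  if (!is.null(graphml)) {
    igraph::write_graph(net$graph, graphml, format = "graphml")
  }
  if (!is.null(edgelist)) {
    readr::write_tsv(net$edges, edgelist)
  }
  invisible(net)
}
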