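# Clonal structure: MAF profile matrix, informative-mutation selection,
# hierarchical clustering of glands into clone clusters, spatial grid
# mapping and the public / partially shared / private partition.

#' Build a site-by-gland MAF matrix from mutation records
#'
#' Compiles the MAF profile of every mutation site across every gland of one
#' subject. Glands without a record at a site get MAF 0. Sites whose MAF in
#' the matched blood sample exceeds `blood_max` in any gland are excluded as
#' likely germline.
#'
#' @param records Mutation record tibble (one subject).
#' @param glands Optional gland tibble; its `gland_id` order defines the
#'   columns (glands with no mutations still appear).
#' @param blood_max Blood MAF exclusion threshold (default 0.05).
#' @return Numeric matrix, rows = `chrom:pos` sites, columns = glands.
#' @export
maf_matrix <- function(records, glands = NULL, blood_max = 0.05) {
  records <- as_tibble(records)
  records$site <- paste0(records$chrom, ":", records$pos)
  records$maf <- ifelse(records$depth > 0, records$alt_reads / records$depth, 0)
  blood_maf <- ifelse(records$blood_depth > 0,
                      records$blood_alt_reads / records$blood_depth, 0)
  bad <- unique(records$site[blood_maf > blood_max])
  records <- records[!records$site %in% bad, , drop = FALSE]
  gland_ids <- if (is.null(glands)) unique(records$gland_id) else glands$gland_id
  sites <- unique(records$site)
  m <- matrix(0, length(sites), length(gland_ids),
              dimnames = list(sites, gland_ids))
  keep <- records$gland_id %in% gland_ids
  m[cbind(match(records$site[keep], sites),
          match(records$gland_id[keep], gland_ids))] <- records$maf[keep]
  m
}

#' Select informative mutations
#'
#' Retains mutation sites usable for clone clustering: sites whose MAF is at
#' least `clonal_maf` in at least `min_glands` glands. For each retained
#' site, glands at MAF >= `share_maf` are marked as supporting glands
#' (attribute `support`, a logical matrix), implementing the lower
#' co-sharing criterion.
#'
#' @param matrix Site-by-gland MAF matrix (see [maf_matrix()]).
#' @param share_maf Co-sharing MAF threshold (default 0.10).
#' @param clonal_maf Clonal MAF threshold (default 0.25).
#' @param min_glands Minimum glands at clonal MAF (default 2).
#' @return Reduced matrix (possibly 0 rows, with a warning when nothing
#'   passes) with the `support` attribute.
#' @export
select_informative_mutations <- function(matrix, share_maf = 0.10,
                                         clonal_maf = 0.25, min_glands = 2) {
  if (!nrow(matrix)) stop("empty MAF matrix", call. = FALSE)
  keep <- rowSums(matrix >= clonal_maf) >= min_glands
  if (!any(keep)) warning("no informative mutation sites pass the criteria")
  out <- matrix[keep, , drop = FALSE]
  attr(out, "support") <- out >= share_maf
  out
}

cluster_members_rec <- function(merge, height, node, labels) {
  # returns leaf indices under a merge-tree node (negative = leaf)
  if (node < 0) return(-node)
  c(cluster_members_rec(merge, height, merge[node, 1], labels),
    cluster_members_rec(merge, height, merge[node, 2], labels))
}

#' Cluster glands into putative clone clusters
#'
#' Agglomerative clustering (default average linkage, Euclidean distance) of
#' the gland MAF profiles, followed by a defining-mutation rule: descending
#' from the dendrogram root, a subtree is accepted as a clone cluster when
#' all of its glands share at least `min_shared` mutations at MAF >=
#' `clonal_maf`. Glands in no accepted subtree are singletons. A cluster is
#' defined by shared clonal mutations rather than by a dendrogram height
#' cut, so cluster calls do not depend on a tuned cut height.
#'
#' @param matrix Site-by-gland MAF matrix (ideally after
#'   [select_informative_mutations()]).
#' @param linkage,metric Passed to `hclust()` / `dist()`.
#' @param min_shared Minimum number of defining mutations (default 2).
#' @param clonal_maf Defining-mutation MAF threshold (default 0.25).
#' @return A `clone_clusters` object: list with `assignments` (tibble
#'   `gland_id`, `cluster_id`, `NA` = singleton), `clusters` (tibble
#'   `cluster_id`, `n_glands`, `n_defining`, `members`, `defining_sites` as
#'   list-columns) and the `hclust` tree. `tidy()` returns the assignments.
#' @export
cluster_glands <- function(matrix, linkage = "average", metric = "euclidean",
                           min_shared = 2, clonal_maf = 0.25) {
  if (ncol(matrix) < 2) stop("need at least two glands", call. = FALSE)
  labels <- colnames(matrix)
  d <- dist(t(matrix), method = metric)
  hc <- hclust(d, method = linkage)

  accepted <- list()
  visit <- function(node) {
    idx <- if (node < 0) -node else
      cluster_members_rec(hc$merge, hc$height, node, labels)
    if (length(idx) >= 2) {
      defining <- which(rowSums(matrix[, idx, drop = FALSE] >= clonal_maf) == length(idx))
      if (length(defining) >= min_shared) {
        accepted[[length(accepted) + 1]] <<- list(idx = idx, defining = defining)
        return(invisible())
      }
    }
    if (node > 0) {
      visit(hc$merge[node, 1])
      visit(hc$merge[node, 2])
    }
    invisible()
  }
  visit(nrow(hc$merge))

  assignments <- tibble(gland_id = labels, cluster_id = NA_character_)
  clusters <- tibble(cluster_id = character(), n_glands = integer(),
                     n_defining = integer(), members = list(),
                     defining_sites = list())
  for (i in seq_along(accepted)) {
    cid <- paste0("cluster", i)
    idx <- accepted[[i]]$idx
    assignments$cluster_id[idx] <- cid
    clusters <- dplyr::bind_rows(clusters, tibble(
      cluster_id = cid, n_glands = length(idx),
      n_defining = length(accepted[[i]]$defining),
      members = list(labels[idx]),
      defining_sites = list(rownames(matrix)[accepted[[i]]$defining])
    ))
  }
  structure(list(assignments = assignments, clusters = clusters,
                 tree = hc, matrix = matrix),
            class = "clone_clusters")
}

#' @export
print.clone_clusters <- function(x, ...) {
  cat("<clone_clusters>", nrow(x$clusters), "cluster(s) over",
      nrow(x$assignments), "glands;",
      sum(is.na(x$assignments$cluster_id)), "singleton(s)\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.clone_clusters <- function(x, ...) x$assignments

#' @exportS3Method generics::glance
glance.clone_clusters <- function(x, ...) {
  tibble(n_glands = nrow(x$assignments), n_clusters = nrow(x$clusters),
         n_singletons = sum(is.na(x$assignments$cluster_id)))
}

grid_components <- function(rows, cols) {
  # connected components under the 4-neighborhood; returns component ids
  n <- length(rows)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(is.na(comp) &
                    abs(rows - rows[i]) + abs(cols - cols[i]) == 1)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Map clone clusters onto the spatial grid
#'
#' Computes each cluster's grid footprint (the set of occupied grid cells)
#' and whether that footprint is contiguous under the 4-neighborhood of the
#' rectangular lattice. Glands without a grid assignment are excluded from
#' the footprint with a warning.
#'
#' @param clusters A `clone_clusters` object.
#' @param glands Gland tibble with `gland_id`, `grid_id`, `grid_row`,
#'   `grid_col`.
#' @return Tibble: `cluster_id`, `n_glands`, `footprint` (list of grid ids),
#'   `footprint_size`, `contiguous`.
#' @export
map_clusters_to_grid <- function(clusters, glands) {
  glands <- as_tibble(glands)
  asg <- dplyr::left_join(clusters$assignments, glands, by = "gland_id")
  asg <- asg[!is.na(asg$cluster_id), , drop = FALSE]
  if (any(is.na(asg$grid_id))) {
    warning(sum(is.na(asg$grid_id)), " gland(s) lack grid assignments and were excluded")
    asg <- asg[!is.na(asg$grid_id), , drop = FALSE]
  }
  out <- lapply(split(asg, asg$cluster_id), function(d) {
    cells <- unique(d[, c("grid_id", "grid_row", "grid_col")])
    tibble(cluster_id = d$cluster_id[1], n_glands = nrow(d),
           footprint = list(sort(cells$grid_id)),
           footprint_size = nrow(cells),
           contiguous = length(unique(
             grid_components(cells$grid_row, cells$grid_col))) == 1)
  })
  dplyr::bind_rows(out)
}

#' Classify mutation sharing within a clone cluster
#'
#' Partitions the cluster's mutations by presence pattern: public (present
#' in all member glands), partially shared (present in more than one but not
#' all), private (present in exactly one). Presence means MAF >=
#' `presence_maf`. Sites present in no member are not counted as cluster
#' mutations.
#'
#' @param matrix Site-by-gland MAF matrix.
#' @param members Character vector of the cluster's gland ids (>= 2).
#' @param presence_maf Presence threshold (default 0.25, the clonal MAF
#'   threshold).
#' @return A `sharing_profile`: tibble (`site`, `n_present`, `label`) with
#'   the counts `mb_pub`, `mb_ps`, `mb_priv` as attributes (also via
#'   `sharing_counts()`).
#' @export
classify_sharing <- function(matrix, members, presence_maf = 0.25) {
  stopifnot(length(members) >= 2, all(members %in% colnames(matrix)))
  sub <- matrix[, members, drop = FALSE]
  n_present <- rowSums(sub >= presence_maf)
  keep <- n_present > 0
  label <- ifelse(n_present == length(members), "public",
                  ifelse(n_present == 1, "private", "partial"))
  out <- tibble(site = rownames(sub)[keep],
                n_present = unname(n_present[keep]),
                label = unname(label[keep]))
  structure(out, class = c("sharing_profile", class(out)),
            counts = c(mb_pub = sum(out$label == "public"),
                       mb_ps = sum(out$label == "partial"),
                       mb_priv = sum(out$label == "private")))
}

#' @rdname classify_sharing
#' @param profile A `sharing_profile`.
#' @export
sharing_counts <- function(profile) attr(profile, "counts")
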