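links_path <- function(path) {
  sub("(\\.[A-Za-z0-9]+)?$", ".links.tsv", path)
}

#' Write / read a cluster set as TSV
#'
#' `write_clusters()` emits one row per member with columns `cluster_id`,
#' `level`, `seed_id`, `representative_id`, `member_id`, sorted by
#' cluster id then member id (UTF-8, LF endings, deterministic). Parent/child
#' links go to a companion file (`<path minus extension>.links.tsv`, columns
#' `cluster_id`, `child_cluster_id`) when any cluster has children.
#' `read_clusters()` reverses the writer and re-validates the partition, so
#' `read_clusters(write_clusters(x))` reproduces `x` exactly.
#'
#' @param clusters A [cluster_set()].
#' @param path Output TSV path.
#' @return `write_clusters()` returns `path` invisibly; `read_clusters()`
#'   returns a [cluster_set()].
#' @export
write_clusters <- function(clusters, path) {
  rows <- do.call(rbind, c(
    lapply(clusters$clusters, function(cl) {
      data.frame(
        cluster_id = cl$cluster_id, level = cl$level, seed_id = cl$seed_id,
        representative_id = cl$representative_id, member_id = cl$member_ids,
        stringsAsFactors = FALSE
      )
    }),
    list(data.frame(
      cluster_id = character(), level = integer(), seed_id = character(),
      representative_id = character(), member_id = character()
    ))
  ))
  rows <- rows[order(rows$cluster_id, rows$member_id), , drop = FALSE]
  con <- file(path, open = "wb") # LF endings on every platform
  on.exit(close(con))
  write.table(rows, con,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8", eol = "\n"
  )
  links <- do.call(rbind, c(
    lapply(clusters$clusters, function(cl) {
      if (!length(cl$child_cluster_ids)) {
        return(NULL)
      }
      data.frame(
        cluster_id = cl$cluster_id, child_cluster_id = cl$child_cluster_ids,
        stringsAsFactors = FALSE
      )
    }),
    list(NULL)
  ))
  if (!is.null(links) && nrow(links)) {
    links <- links[order(links$cluster_id, links$child_cluster_id), , drop = FALSE]
    lcon <- file(links_path(path), open = "wb")
    on.exit(close(lcon), add = TRUE)
    write.table(links, lcon,
      sep = "\t", quote = FALSE, row.names = FALSE,
      fileEncoding = "UTF-8", eol = "\n"
    )
  }
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  if (!file.exists(path)) rc_format_error(paste0("no such file: ", path))
  rows <- read.delim(path, stringsAsFactors = FALSE, colClasses = list(member_id = "character", cluster_id = "character", seed_id = "character", representative_id = "character"))
  need <- c("cluster_id", "level", "seed_id", "representative_id", "member_id")
  if (!all(need %in% names(rows))) {
    rc_format_error(paste0(
      "cluster file ", path, " must have columns: ", paste(need, collapse = ", ")
    ))
  }
  if (nrow(rows) == 0L) {
    return(cluster_set(NA_integer_, list()))
  }
  if (length(unique(rows$level)) > 1L) {
    rc_format_error("a cluster file must hold a single identity level")
  }
  per_cluster <- split(rows, rows$cluster_id)
  for (ci in names(per_cluster)) {
    if (length(unique(per_cluster[[ci]]$seed_id)) > 1L ||
      length(unique(per_cluster[[ci]]$representative_id)) > 1L) {
      rc_format_error(paste0("conflicting seed/representative rows for ", ci))
    }
  }
  dup <- unique(rows$member_id[duplicated(rows$member_id)])
  if (length(dup)) {
    rc_validation_error(paste0(
      "member(s) listed in more than one cluster: ", paste(dup, collapse = ", ")
    ))
  }
  lp <- links_path(path)
  links <- if (file.exists(lp)) {
    read.delim(lp, stringsAsFactors = FALSE)
  } else {
    data.frame(cluster_id = character(), child_cluster_id = character())
  }
  clusters <- lapply(per_cluster, function(g) {
    new_cluster(
      level = g$level[1], seed_id = g$seed_id[1],
      representative_id = g$representative_id[1], member_ids = g$member_id,
      child_cluster_ids = links$child_cluster_id[links$cluster_id == g$cluster_id[1]]
    )
  })
  names(clusters) <- NULL
  cluster_set(rows$level[1], clusters)
}

#' Write a whole hierarchy (three TSV files plus links)
#'
#' Convenience wrapper used by the command-line interface: writes
#' `clusters100.tsv`, `clusters90.tsv`, `clusters50.tsv` (plus `.links.tsv`
#' companions) under `dir`.
#'
#' @param hierarchy A `uniref_hierarchy`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_hierarchy <- function(hierarchy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_clusters(hierarchy$level100, file.path(dir, "clusters100.tsv"))
  write_clusters(hierarchy$level90, file.path(dir, "clusters90.tsv"))
  write_clusters(hierarchy$level50, file.path(dir, "clusters50.tsv"))
  invisible(dir)
}
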