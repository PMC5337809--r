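# Lineage analysis of annotated repertoire reads: V-J family grouping,
# pairwise nucleotide distances, connected-component lineage clustering, and
# a synthetic annotated-read generator with planted ground truth.

#' Group annotated reads by V-J combination
#'
#' Reads sharing a V and J gene assignment form one family; families are
#' ranked by total read count (descending, ties broken lexicographically by
#' label) so the most abundant combinations can be selected.
#'
#' @param reads data frame with columns `read_id`, `sequence`, `v_gene`,
#'   `j_gene`, `cdr3_peptide`, `count` (collapsed duplicate reads, >= 1).
#' @return Named list of read data frames, ordered by family size; names are
#'   `"V-J"` labels.
#' @export
group_by_vj <- function(reads) {
  if (nrow(reads) == 0) return(stats::setNames(list(), character(0)))
  label <- paste(reads$v_gene, reads$j_gene, sep = "-")
  groups <- split(reads, label)
  totals <- vapply(groups, function(g) sum(g$count), numeric(1))
  ord <- order(-totals, names(groups))
  groups[ord]
}

#' Number of differences between two reads
#'
#' Equal-length sequences are compared position by position (Hamming
#' distance), skipping positions where either read has an uncalled base `N`;
#' unequal-length sequences fall back to the Levenshtein edit distance
#' (variable-length pyrosequencing reads carry indels the simple positional
#' count cannot handle).
#'
#' @param a,b nucleotide (or peptide) strings.
#' @return Integer difference count; 0 iff the sequences are identical up to
#'   `N` positions.
#' @export
seq_distance <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    x <- strsplit(a, "")[[1]]
    y <- strsplit(b, "")[[1]]
    ok <- x != "N" & y != "N"
    sum(x[ok] != y[ok])
  } else {
    as.integer(utils::adist(a, b))
  }
}

# full pairwise distance matrix for one family (O(n^2), fine at the scale of
# hundreds of reads per family)
distance_matrix <- function(sequences) {
  n <- length(sequences)
  d <- matrix(0L, n, n)
  if (n < 2) return(d)
  lens <- nchar(sequences)
  chars <- lapply(sequences, function(s) strsplit(s, "")[[1]])
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (lens[i] == lens[j]) {
        x <- chars[[i]]
        y <- chars[[j]]
        ok <- x != "N" & y != "N"
        d[i, j] <- d[j, i] <- sum(x[ok] != y[ok])
      } else {
        d[i, j] <- d[j, i] <- as.integer(utils::adist(sequences[i],
                                                      sequences[j]))
      }
    }
  }
  d
}

#' Cluster one V-J family into lineages
#'
#' Reads are nodes; every pair at distance `max_diff` or less is connected;
#' lineages are the connected components of this graph (connectivity, not
#' cliques: two reads of one lineage may differ by more than `max_diff` if a
#' chain of intermediates links them). Clusters are ranked by total read
#' count so the largest (or k-th largest) lineage can be selected.
#'
#' @param reads data frame of one V-J family (see [group_by_vj()]).
#' @param max_diff maximum pairwise difference joining two reads (default 2).
#' @param level `"nucleotide"` clusters on `sequence`; `"peptide"` on
#'   `cdr3_peptide`.
#' @return List of clusters, each a list with `vj_label`, `rank`,
#'   `member_ids`, `n_subclones` and `total_reads`, sorted by `total_reads`
#'   descending (ties: smaller first member id first).
#' @export
cluster_lineages <- function(reads, max_diff = 2,
                             level = c("nucleotide", "peptide")) {
  level <- match.arg(level)
  if (nrow(reads) == 0) stop("empty read group")
  seqs <- if (level == "nucleotide") reads$sequence else reads$cdr3_peptide
  d <- distance_matrix(seqs)
  adj <- d <= max_diff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  vj <- paste(reads$v_gene[1], reads$j_gene[1], sep = "-")
  clusters <- lapply(split(seq_len(nrow(reads)), comp), function(idx) {
    list(vj_label = vj,
         member_ids = reads$read_id[idx],
         n_subclones = length(idx),
         total_reads = sum(reads$count[idx]),
         min_index = min(idx))
  })
  ord <- order(-vapply(clusters, `[[`, numeric(1), "total_reads"),
               vapply(clusters, `[[`, numeric(1), "min_index"))
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) {
    clusters[[i]]$rank <- i
    clusters[[i]]$min_index <- NULL
  }
  unname(clusters)
}

#' Full lineage pipeline over a repertoire
#'
#' Groups reads by V-J, clusters each of the `n_families` most abundant
#' families into lineages, and returns a tidy per-read table.
#'
#' @param reads annotated read data frame.
#' @param n_families number of top V-J families to analyze (default 3, the
#'   number used for the lymph-node comparison; `Inf` for all).
#' @inheritParams cluster_lineages
#' @return Data frame: `read_id`, `vj`, `cluster_rank`, `cluster_size`
#'   (subclones), `cluster_reads`.
#' @export
lineage_table <- function(reads, n_families = 3, max_diff = 2,
                          level = c("nucleotide", "peptide")) {
  level <- match.arg(level)
  groups <- group_by_vj(reads)
  groups <- groups[seq_len(min(n_families, length(groups)))]
  rows <- list()
  for (g in groups) {
    for (cl in cluster_lineages(g, max_diff = max_diff, level = level)) {
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = cl$member_ids, vj = cl$vj_label, cluster_rank = cl$rank,
        cluster_size = cl$n_subclones, cluster_reads = cl$total_reads)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(read_id = character(0), vj = character(0),
                      cluster_rank = integer(0), cluster_size = integer(0),
                      cluster_reads = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic annotated repertoire with planted lineages
#'
#' Emulates the structure of a lymph-node repertoire-sequencing sample: a
#' handful of V-J families, each containing one or more lineages whose
#' members derive from a random founder sequence by small numbers of point
#' substitutions, with a heavy-tailed read-count distribution (most
#' subclones at count 1, a few expanded). Lineage founders within a family
#' are mutually distant, so the planted partition is recoverable by
#' clustering. Ground-truth labels travel with each read.
#'
#' @param n_families number of V-J families (default 3).
#' @param lineages_per_family lineages planted in each family (default 2).
#' @param reads_per_lineage unique subclones per lineage (default 30).
#' @param founder_length founder sequence length in nt (default 300).
#' @param mutation_rate mean substitutions per read relative to its lineage
#'   founder (Poisson, capped at `max_mutations`; default 1).
#' @param max_mutations cap on substitutions per read (default 2, the
#'   clustering radius, so every read connects to its lineage founder and
#'   the planted partition is recoverable by construction).
#' @param expanded_per_lineage leading subclones per lineage given an
#'   expanded read count (default 1: the unmutated lineage founder).
#' @param expanded_count read count of each expanded subclone (default 40).
#' @param count_tail_p geometric tail parameter of background counts: counts
#'   are 1 + rgeom(p), concentrating on 1 (default 0.8).
#' @return Data frame of annotated reads (`read_id`, `sequence`, `v_gene`,
#'   `j_gene`, `cdr3_peptide`, `count`) with ground-truth columns
#'   `true_family` and `true_lineage`.
#' @export
synth_repertoire <- function(n_families = 3, lineages_per_family = 2,
                             reads_per_lineage = 30, founder_length = 300,
                             mutation_rate = 1, max_mutations = 2,
                             expanded_per_lineage = 1,
                             expanded_count = 40, count_tail_p = 0.8) {
  bases <- c("A", "C", "G", "T")
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rows <- list()
  for (f in seq_len(n_families)) {
    v <- sprintf("V%d", f)
    j <- sprintf("J%d", ((f - 1) %% 4) + 1)
    for (l in seq_len(lineages_per_family)) {
      # independent random founders: at 300 nt, two random sequences differ
      # at ~225 positions, far beyond any clustering radius
      founder <- sample(bases, founder_length, replace = TRUE)
      cdr3_founder <- sample(aas, 12, replace = TRUE)
      for (r in seq_len(reads_per_lineage)) {
        s <- founder
        # the first read is the unmutated lineage founder; later reads carry
        # up to max_mutations substitutions, keeping them within the
        # clustering radius of the founder
        m <- if (r == 1) 0L else min(stats::rpois(1, mutation_rate),
                                     max_mutations, founder_length)
        if (m > 0) {
          pos <- sample.int(founder_length, m)
          for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
        }
        pep <- cdr3_founder
        if (m > 0 && stats::runif(1) < 0.3) {
          q <- sample.int(length(pep), 1)
          pep[q] <- sample(setdiff(aas, pep[q]), 1)
        }
        cnt <- if (r <= expanded_per_lineage) {
          expanded_count
        } else {
          1L + stats::rgeom(1, count_tail_p)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = sprintf("F%dL%dR%03d", f, l, r),
          sequence = paste(s, collapse = ""),
          v_gene = v, j_gene = j,
          cdr3_peptide = paste(pep, collapse = ""),
          count = as.integer(cnt),
          true_family = paste(v, j, sep = "-"),
          true_lineage = sprintf("F%dL%d", f, l)
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an annotated repertoire from FASTA plus annotation table
#'
#' @param fasta path to a (plain-text) FASTA of nucleotide reads; names must
#'   match `read_id` in the annotation table.
#' @param annotations path to a tab-delimited table with header
#'   `read_id  v_gene  j_gene  cdr3_peptide  count` (`count` optional,
#'   defaults to 1).
#' @return Annotated read data frame (see [group_by_vj()]).
#' @export
read_repertoire <- function(fasta, annotations) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ann <- utils::read.delim(annotations, stringsAsFactors = FALSE)
  need <- c("read_id", "v_gene", "j_gene", "cdr3_peptide")
  if (!all(need %in% names(ann))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(ann$count)) ann$count <- 1L
  miss <- setdiff(ann$read_id, names(seqs))
  if (length(miss)) {
    stop("reads missing from FASTA: ", paste(utils::head(miss, 5),
                                             collapse = ", "))
  }
  ann$sequence <- as.character(seqs[ann$read_id])
  ann[, c("read_id", "sequence", "v_gene", "j_gene", "cdr3_peptide", "count")]
}

#' Write an annotated repertoire to FASTA plus annotation table
#'
#' @param reads annotated read data frame.
#' @param fasta,annotations output paths.
#' @return Invisibly, the two paths.
#' @export
write_repertoire <- function(reads, fasta, annotations) {
  seqs <- Biostrings::DNAStringSet(stats::setNames(reads$sequence,
                                                   reads$read_id))
  Biostrings::writeXStringSet(seqs, fasta)
  utils::write.table(
    reads[, setdiff(names(reads), "sequence")], annotations,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, annotations = annotations))
}
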