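#' Pairwise sequence identity from a global alignment
#'
#' End-to-end (Needleman--Wunsch/Gotoh) alignment under match = +1,
#' mismatch = -1, gap open = -2, gap extend = -1 (a gap of length L scores
#' `-2 - (L - 1)`). Identity is matching columns divided by alignment
#' columns; by default gaps count against identity
#' (`identity_mode = "all_columns"`), the alternative excludes terminal gap
#' columns. Symmetric in its arguments.
#'
#' @param a,b sequence strings (or single-row data.frames with `sequence`).
#' @param identity_mode `"all_columns"` (default) or `"ignore_terminal_gaps"`.
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, identity_mode = c("all_columns", "ignore_terminal_gaps")) {
  identity_mode <- match.arg(identity_mode)
  a <- as_seq_string(a); b <- as_seq_string(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  if (identity_mode == "all_columns") {
    return(align_global_cpp(a, b)$identity)
  }
  # ignore terminal gaps: align, then trim flanking gap columns. Recompute
  # via the shorter-vs-substring trick is not exact; instead redo alignment
  # in R to get the column strings (sequences in scope are short).
  al <- align_global_r(a, b)
  gap_a <- al$a_aln == "-"; gap_b <- al$b_aln == "-"
  ncol <- length(gap_a)
  lead <- match(FALSE, gap_a | gap_b) - 1
  trail <- ncol - max(which(!(gap_a | gap_b)))
  keep <- seq.int(lead + 1, ncol - trail)
  sum(al$a_aln[keep] == al$b_aln[keep]) / length(keep)
}

as_seq_string <- function(x) {
  if (is.data.frame(x)) x <- x$sequence
  as.character(x)[1]
}

#' Greedy centroid clustering at an identity threshold
#'
#' Reimplements greedy centroid-based OTU clustering: sequences are
#' processed in order of decreasing length (ties by input order); each query
#' is compared to the existing centroids in the order the centroids were
#' created and joins the first centroid (`accept_mode = "first"`) or the
#' best centroid (`accept_mode = "best"`) with identity >= `threshold`;
#' otherwise it founds a new cluster. The centroid of a cluster is therefore
#' always its longest member.
#'
#' @param seqs data.frame with `id`, `sequence` (e.g. from [read_fasta()]).
#' @param threshold identity threshold in `(0, 1]` (0.97 in typical barcode use).
#' @param accept_mode `"first"` or `"best"`.
#' @param identity_mode passed to [pairwise_identity()].
#' @return data.frame with columns `otu_id`, `centroid_id`, `member_id`,
#'   members in assignment order.
#' @export
greedy_cluster <- function(seqs, threshold = 0.97,
                           accept_mode = c("first", "best"),
                           identity_mode = "all_columns") {
  accept_mode <- match.arg(accept_mode)
  if (!is.data.frame(seqs) || !nrow(seqs)) stop("no sequences", call. = FALSE)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  len <- nchar(seqs$sequence)
  ord <- order(-len, seq_len(nrow(seqs)))
  centroids <- integer(0)       # row indices of centroids, creation order
  assign_to <- integer(nrow(seqs))
  for (i in ord) {
    hit <- 0L; best_id <- -1
    for (ci in seq_along(centroids)) {
      idy <- pairwise_identity(seqs$sequence[i], seqs$sequence[centroids[ci]],
                               identity_mode = identity_mode)
      if (idy >= threshold) {
        if (accept_mode == "first") { hit <- ci; break }
        if (idy > best_id) { best_id <- idy; hit <- ci }
      }
    }
    if (hit > 0L) {
      assign_to[i] <- hit
    } else {
      centroids <- c(centroids, i)
      assign_to[i] <- length(centroids)
    }
  }
  out <- data.frame(
    otu_id = paste0("OTU", assign_to),
    centroid_id = seqs$id[centroids[assign_to]],
    member_id = seqs$id,
    stringsAsFactors = FALSE)
  # report members in assignment (length) order within input order
  out[ord, , drop = FALSE][order(assign_to[ord]), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

# Plain-R global aligner returning the aligned column vectors; same scoring
# and tie-break as the C++ aligner. Used for the terminal-gap identity mode
# and kept deliberately simple.
align_global_r <- function(a, b, match = 1, mismatch = -1,
                           gap_open = -2, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv); NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n) X[2:(n + 1), 1] <- gap_open + (0:(n - 1)) * gap_extend
  if (m) Y[1, 2:(m + 1)] <- gap_open + (0:(m - 1)) * gap_extend
  for (i in 2:(n + 1)) {
    s_row <- ifelse(av[i - 1] == bv, match, mismatch)
    for (j in 2:(m + 1)) {
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s_row[j - 1]
      X[i, j] <- max(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend,
                     Y[i - 1, j] + gap_open)
      Y[i, j] <- max(M[i, j - 1] + gap_open, Y[i, j - 1] + gap_extend,
                     X[i, j - 1] + gap_open)
    }
  }
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  a_aln <- character(0); b_aln <- character(0)
  while (i > 1 || j > 1) {
    if (state == 1) {
      a_aln <- c(av[i - 1], a_aln); b_aln <- c(bv[j - 1], b_aln)
      prev <- M[i, j] - ifelse(av[i - 1] == bv[j - 1], match, mismatch)
      i <- i - 1; j <- j - 1
      if (i == 1 && j == 1) break
      state <- if (abs(M[i, j] - prev) < 1e-9) 1
      else if (abs(X[i, j] - prev) < 1e-9) 2 else 3
    } else if (state == 2) {
      cur <- X[i, j]; i <- i - 1
      a_aln <- c(av[i], a_aln); b_aln <- c("-", b_aln)
      state <- if (abs(M[i, j] + gap_open - cur) < 1e-9) 1
      else if (abs(X[i, j] + gap_extend - cur) < 1e-9) 2 else 3
    } else {
      cur <- Y[i, j]; j <- j - 1
      a_aln <- c("-", a_aln); b_aln <- c(bv[j], b_aln)
      state <- if (abs(M[i, j] + gap_open - cur) < 1e-9) 1
      else if (abs(Y[i, j] + gap_extend - cur) < 1e-9) 3 else 2
    }
  }
  list(a_aln = a_aln, b_aln = b_aln)
}
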