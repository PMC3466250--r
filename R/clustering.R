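#' Greedy incremental identity clustering
#'
#' cd-hit-style clustering: sequences are sorted longest-first (ties broken
#' by identifier) and each sequence joins the first existing cluster whose
#' representative it matches at `identity` over an alignment covering at
#' least `coverage` of the shorter sequence, else it seeds a new cluster.
#' Identity is matches / alignment-length of a semi-global alignment of the
#' shorter sequence against the representative (end gaps on the longer
#' sequence free).  A k-mer count prefilter (8-mers for nucleotide, 4-mers
#' for protein) skips alignments that cannot reach the threshold: a match at
#' identity i over coverage c of a length-L sequence must share at least
#' c*L - k + 1 - k*(1-i)*L of its k-mers with the representative (each edit
#' destroys at most k words); the bound is relaxed by a further factor 1.5
#' on the edit term, so the filter is lossless and never changes the
#' partition.
#'
#' @param seqs named character vector (or [seq_records]) of sequences.
#' @param identity minimum global identity, in (0, 1].
#' @param coverage minimum aligned fraction of the shorter sequence, in
#'   (0, 1].
#' @param mode `"nucleotide"` or `"protein"` (sets the prefilter k-mer size).
#' @param prefilter disable to force all alignments (oracle comparisons).
#' @return data.frame with one row per sequence: `rep_id`, `member_id`,
#'   `identity` (1 for the representative itself), ordered by cluster then
#'   member.
#' @export
greedy_cluster <- function(seqs, identity, coverage,
                           mode = c("nucleotide", "protein"),
                           prefilter = TRUE) {
  mode <- match.arg(mode)
  if (inherits(seqs, "seq_records")) seqs <- setNames(seqs$residues, seqs$id)
  if (identity <= 0 || identity > 1 || coverage <= 0 || coverage > 1)
    stop("identity and coverage must lie in (0, 1]")
  if (length(seqs) == 0L)
    return(data.frame(rep_id = character(0), member_id = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  k <- if (mode == "nucleotide") 8L else 4L
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[ord]
  reps <- integer(0)               # indices into seqs
  rep_kmers <- list()
  assign_rep <- integer(length(seqs))
  assign_idy <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    sk <- if (prefilter && nchar(s) >= k)
      unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))) else NULL
    need <- kmer_count_bound(nchar(s), k, identity, coverage)
    placed <- FALSE
    for (r in seq_along(reps)) {
      if (prefilter && !is.null(sk) &&
          sum(sk %in% rep_kmers[[r]]) < need) next
      al <- glocal_align_cpp(s, seqs[[reps[r]]])
      idy <- if (al$aln_len > 0L) al$matches / al$aln_len else 0
      covered <- al$aln_len >= coverage * nchar(s)
      if (idy >= identity && covered) {
        assign_rep[i] <- reps[r]; assign_idy[i] <- idy
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      rep_kmers <- c(rep_kmers, list(
        if (nchar(s) >= k)
          unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
        else character(0)))
      assign_rep[i] <- i; assign_idy[i] <- 1
    }
  }
  data.frame(rep_id = names(seqs)[assign_rep],
             member_id = names(seqs),
             identity = assign_idy,
             stringsAsFactors = FALSE)
}

# minimum distinct k-mers a qualifying member must share with its
# representative; lossless (each of the <= (1-identity)*L edits destroys at
# most k words; slack factor 1.5 absorbs gap columns and repeated words)
kmer_count_bound <- function(len, k, identity, coverage) {
  need <- floor(coverage * len) - k + 1L -
    ceiling(1.5 * k * (1 - identity) * len)
  max(1L, as.integer(need))
}

#' Cluster representatives
#'
#' @param clusters output of [greedy_cluster()].
#' @return character vector of representative ids.
#' @export
cluster_reps <- function(clusters) unique(clusters$rep_id)

#' Two-set clustering: remove query sequences matching a reference set
#'
#' Used to exclude noncoding transcripts that are really UTR fragments of
#' protein-coding transcripts: query sequences matching any reference
#' sequence at the thresholds (coverage measured on the shorter of the two)
#' are removed; the survivors are then clustered among themselves with
#' [greedy_cluster()].
#'
#' @param query_set,reference_set named character vectors (or
#'   [seq_records]) of nucleotide sequences.
#' @param identity,coverage thresholds as in [greedy_cluster()].
#' @return list with `retained` (query ids surviving the screen), `removed`
#'   (query ids absorbed by the reference) and `clusters` (partition of the
#'   survivors).
#' @export
cluster_two_sets <- function(query_set, reference_set,
                             identity = 0.98, coverage = 0.95) {
  if (inherits(query_set, "seq_records"))
    query_set <- setNames(query_set$residues, query_set$id)
  if (inherits(reference_set, "seq_records"))
    reference_set <- setNames(reference_set$residues, reference_set$id)
  k <- 8L
  ref_kmers <- lapply(reference_set, function(s)
    if (nchar(s) >= k) unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
    else character(0))
  removed <- character(0)
  for (qid in names(query_set)) {
    q <- query_set[[qid]]
    qk <- if (nchar(q) >= k)
      unique(substring(q, 1:(nchar(q) - k + 1L), k:nchar(q))) else character(0)
    for (rid in names(reference_set)) {
      shorter_len <- min(nchar(q), nchar(reference_set[[rid]]))
      need <- kmer_count_bound(shorter_len, k, identity, coverage)
      if (sum(qk %in% ref_kmers[[rid]]) < need) next
      r <- reference_set[[rid]]
      shorter <- if (nchar(q) <= nchar(r)) q else r
      longer <- if (nchar(q) <= nchar(r)) r else q
      al <- glocal_align_cpp(shorter, longer)
      idy <- if (al$aln_len > 0L) al$matches / al$aln_len else 0
      if (idy >= identity && al$aln_len >= coverage * nchar(shorter)) {
        removed <- c(removed, qid)
        break
      }
    }
  }
  retained <- setdiff(names(query_set), removed)
  clusters <- greedy_cluster(query_set[retained], identity, coverage,
                             mode = "nucleotide")
  list(retained = retained, removed = removed, clusters = clusters)
}
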