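TISSUES <- c("gills", "intestine", "kidney", "liver", "spleen", "testis")

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE != "*"], character(0))
STOP_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

#' Simulator configuration
#'
#' Parameters of the synthetic oligo-capped library.  Length fields are
#' sampling functions `function(n)` returning integers so any distribution
#' can be plugged in; the defaults emulate a short-insert full-length cDNA
#' library: inserts mostly 0.5-1.5 kb, Sanger reads 550-750 bases with a
#' low-quality tail, substitution-only errors, and a poly(A)-signal
#' composition equal to the observed usage in non-redundant protein-coding
#' transcripts (renormalised over the 15 identifiable signals).
#'
#' @param n_genes number of genes (one clone each).
#' @param noncoding_frac fraction of genes whose transcript carries no CDS.
#' @param cds_len_dist CDS length sampler (codons, incl. start and stop).
#' @param utr5_len_dist,utr3_len_dist UTR length samplers (bases; the 3'
#'   value is the stretch before the polyadenylation signal).
#' @param nc_len_dist body-length sampler for noncoding transcripts.
#' @param signal_distribution named probability vector over the 15 signal
#'   hexamers (RNA alphabet); must sum to 1.
#' @param tail_len_dist poly(A)-tail length sampler.
#' @param truncation_prob probability a molecule is 5'-truncated (truncated
#'   molecules cannot be cap-ligated and carry no cap tag).
#' @param error_rate per-base substitution rate in reads.
#' @param read_len_dist Sanger read-length sampler.
#' @param size_window insert size-selection window `(min, max)` in bases.
#' @param tissues tissue labels assigned to clones.
#' @param seed integer seed; identical seeds give byte-identical libraries.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 200,
                       noncoding_frac = 0.4,
                       cds_len_dist = function(n) sample(100:350, n, TRUE),
                       utr5_len_dist = function(n) sample(20:150, n, TRUE),
                       utr3_len_dist = function(n) sample(60:400, n, TRUE),
                       nc_len_dist = function(n) sample(400:1200, n, TRUE),
                       signal_distribution = default_signal_distribution(),
                       tail_len_dist = function(n) sample(15:40, n, TRUE),
                       truncation_prob = 0.2,
                       error_rate = 0.005,
                       read_len_dist = function(n) sample(550:750, n, TRUE),
                       size_window = c(500, 3500),
                       tissues = TISSUES,
                       seed = 1L) {
  if (abs(sum(signal_distribution) - 1) > 1e-9)
    stop("signal_distribution probabilities must sum to 1")
  if (!all(names(signal_distribution) %in% polya_signal_hexamers()))
    stop("unknown signal hexamer in signal_distribution")
  structure(list(n_genes = n_genes, noncoding_frac = noncoding_frac,
                 cds_len_dist = cds_len_dist, utr5_len_dist = utr5_len_dist,
                 utr3_len_dist = utr3_len_dist, nc_len_dist = nc_len_dist,
                 signal_distribution = signal_distribution,
                 tail_len_dist = tail_len_dist,
                 truncation_prob = truncation_prob, error_rate = error_rate,
                 read_len_dist = read_len_dist, size_window = size_window,
                 tissues = tissues, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default simulated signal composition
#'
#' Usage proportions of the 15 identifiable polyadenylation-signal hexamers
#' observed in non-redundant full-length protein-coding transcripts (see
#' [polya_signal_reference()]), renormalised to sum to 1.
#'
#' @return Named probability vector (RNA-alphabet hexamers).
#' @export
default_signal_distribution <- function() {
  ref <- polya_signal_reference()
  ref <- ref[ref$signal != "NOT_IDENTIFIABLE", ]
  setNames(ref$coding_n / sum(ref$coding_n), ref$signal)
}

#' Generate a synthetic transcriptome with ground truth
#'
#' Coding genes get a CDS (ATG + random sense codons + stop) flanked by
#' UTRs; noncoding genes a random body.  Every transcript ends with one
#' planted polyadenylation-signal hexamer, a gap of 5-30 random bases and a
#' poly(A) tail, so the signal scan has a known answer for every molecule.
#'
#' @param config a [sim_config()].
#' @return list with `mrnas` (a [seq_records]; ids `g###`), `proteins`
#'   (named character vector, coding genes only) and `genes` (data.frame of
#'   per-gene truth: `gene_id`, `coding`, `cds_start`, `cds_end` (0-based
#'   half-open on the mRNA), `signal`, `gap`, `tail_len`, `mrna_len`).
#' @export
make_transcriptome <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  ids <- sprintf("g%04d", seq_len(n))
  coding <- runif(n) >= config$noncoding_frac
  ncod <- config$cds_len_dist(n)
  u5 <- config$utr5_len_dist(n)
  u3 <- config$utr3_len_dist(n)
  ncl <- config$nc_len_dist(n)
  sigs <- sample(names(config$signal_distribution), n, TRUE,
                 prob = config$signal_distribution)
  gaps <- sample(5:30, n, TRUE)
  tails <- config$tail_len_dist(n)
  mrna <- character(n)
  prot <- character(n)
  cds_start <- rep(NA_integer_, n); cds_end <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (coding[i]) {
      body_cod <- sample(SENSE_CODONS, ncod[i] - 2L, TRUE)
      cds <- paste0("ATG", paste(body_cod, collapse = ""),
                    sample(STOP_CODONS, 1L))
      # an in-frame stop directly upstream of the start codon keeps the
      # 5'UTR free of upstream ORFs, so the true start is unambiguous
      up <- random_dna(u5[i])
      up <- paste0(substr(up, 1L, u5[i] - 3L), "TAA")
      down <- random_dna(u3[i])
      cds_start[i] <- u5[i]
      cds_end[i] <- u5[i] + nchar(cds)
      body <- paste0(up, cds, down)
      prot[i] <- translate_cds(paste0("ATG", paste(body_cod, collapse = "")), 1L)
    } else {
      body <- random_dna(ncl[i])
    }
    mrna[i] <- paste0(body, rna_to_dna(sigs[i]), random_dna(gaps[i]),
                      strrep("A", tails[i]))
  }
  proteins <- setNames(prot[coding], ids[coding])
  genes <- data.frame(gene_id = ids, coding = coding,
                      cds_start = cds_start, cds_end = cds_end,
                      signal = sigs, gap = gaps, tail_len = tails,
                      mrna_len = nchar(mrna), stringsAsFactors = FALSE)
  list(mrnas = seq_records(ids, mrna), proteins = proteins, genes = genes)
}

#' Simulate the cloned library and its paired Sanger reads
#'
#' Each molecule is 5'-truncated with probability `truncation_prob` (losing
#' a random prefix and, with it, the ability to be cap-ligated); intact
#' molecules get the cap tag.  The cloned insert is cap tag + molecule +
#' the reverse complement of the poly(T)-primer head, and inserts outside
#' the size-selection window are dropped.  The 5' read is the insert
#' prefix in sense orientation; the 3' read is the reverse complement of
#' the insert suffix (so it begins with the primer head and a T-run).
#' Reads get Q40 qualities with a Q10 tail over the last ~8% of the read
#' and independent substitution errors at `error_rate`.
#'
#' @param tx output of [make_transcriptome()].
#' @param config the same [sim_config()].
#' @return list with `reads` (a [seq_records] of raw paired reads,
#'   `c####_5p`/`c####_3p`) and `truth` (one row per sequenced clone:
#'   identifiers, tissue, `coding`, `full_length`, `cut` bases removed,
#'   molecule/insert geometry, CDS coordinates on the molecule --
#'   `mcds_start` may be negative when truncation cut into the CDS --
#'   signal, gap and tail truth, per-read lengths and Q10-tail lengths).
#' @export
simulate_library <- function(tx, config) {
  set.seed(config$seed + 1000003L)
  genes <- tx$genes
  n <- nrow(genes)
  cap <- CAP_TAG
  primer_rc <- revcomp(POLYT_PRIMER_HEAD)
  truncated <- runif(n) < config$truncation_prob
  tissues <- sample(config$tissues, n, TRUE)
  rl5 <- config$read_len_dist(n)
  rl3 <- config$read_len_dist(n)
  rows <- list(); ids <- character(0); seqs <- character(0); quals <- list()
  tiss <- character(0)
  clone_no <- 0L
  for (i in seq_len(n)) {
    mol <- tx$mrnas$residues[i]
    cut <- 0L
    if (truncated[i]) {
      cut <- sample.int(max(1L, nchar(mol) %/% 2L), 1L)
      mol <- substr(mol, cut + 1L, nchar(mol))
    }
    capped <- !truncated[i]
    insert <- paste0(if (capped) cap else "", mol, primer_rc)
    L <- nchar(insert)
    if (L < config$size_window[1L] || L > config$size_window[2L]) next
    clone_no <- clone_no + 1L
    cid <- sprintf("c%04d", clone_no)
    r5l <- min(rl5[i], L); r3l <- min(rl3[i], L)
    q105 <- min(40L, max(15L, round(0.08 * r5l)))
    q103 <- min(40L, max(15L, round(0.08 * r3l)))
    read5 <- substr(insert, 1L, r5l)
    read3 <- revcomp(substr(insert, L - r3l + 1L, L))
    if (config$error_rate > 0) {
      read5 <- mutate_seq(read5, config$error_rate)
      read3 <- mutate_seq(read3, config$error_rate)
    }
    ids <- c(ids, paste0(cid, "_5p"), paste0(cid, "_3p"))
    seqs <- c(seqs, read5, read3)
    quals <- c(quals, list(c(rep(40L, r5l - q105), rep(10L, q105))),
               list(c(rep(40L, r3l - q103), rep(10L, q103))))
    tiss <- c(tiss, tissues[i], tissues[i])
    rows[[length(rows) + 1L]] <- data.frame(
      clone_id = cid, gene_id = genes$gene_id[i], tissue = tissues[i],
      coding = genes$coding[i], full_length = capped, cut = cut,
      mol_len = nchar(mol), cap_len = if (capped) nchar(cap) else 0L,
      insert_len = L,
      mcds_start = if (genes$coding[i]) genes$cds_start[i] - cut else NA_integer_,
      mcds_end = if (genes$coding[i]) genes$cds_end[i] - cut else NA_integer_,
      signal = genes$signal[i], gap = genes$gap[i],
      tail_len = genes$tail_len[i],
      read5_len = r5l, read3_len = r3l, q10_5 = q105, q10_3 = q103,
      stringsAsFactors = FALSE)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(clone_id = character(0))
  list(reads = seq_records(ids, seqs, qualities = quals, tissue = tiss),
       truth = truth)
}

mutate_seq <- function(s, rate) {
  n <- nchar(s)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0L) return(s)
  ch <- strsplit(s, "")[[1L]]
  for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# span of a processed query on the molecule (0-based half-open), from the
# truth geometry: the quality trim removes exactly the Q10 tail, the cap tag
# and poly(T)-primer head are removed by preprocessing, and substitution
# errors never shift coordinates.
query_molecule_span <- function(tr, end) {
  if (end == "5p") {
    a <- 0L
    b <- min(tr$read5_len - tr$q10_5 - tr$cap_len, tr$mol_len)
  } else {
    a <- max(0L, tr$mol_len + nchar(POLYT_PRIMER_HEAD) - tr$read3_len + tr$q10_3)
    b <- tr$mol_len
  }
  c(a, max(a, b))
}

# Overlap of a query with its CDS, snapped inward onto the codon grid.
# cds_start/cds_end are the CDS span in query-local coordinates (the start
# may be negative when the query begins inside the CDS); plen is the protein
# length in aa (the CDS interval includes the stop codon, which is excluded
# from the amino-acid interval).  Returns NA fields when no codon overlaps.
cds_overlap_aa <- function(cds_start, cds_end, q_len, plen) {
  empty <- list(aa_s = NA_integer_, aa_e = NA_integer_,
                q_start = NA_integer_, q_end = NA_integer_)
  if (is.na(cds_start) || is.na(cds_end)) return(empty)
  x <- max(0L, cds_start)
  x <- cds_start + 3L * as.integer(ceiling((x - cds_start) / 3))
  y <- min(q_len, cds_end)
  if (y < x + 3L) return(empty)
  y <- cds_start + 3L * ((y - cds_start) %/% 3L)
  aa_s <- (x - cds_start) %/% 3L
  aa_e <- min((y - cds_start) %/% 3L, plen)
  if (aa_e <= aa_s) return(empty)
  list(aa_s = aa_s, aa_e = aa_e, q_start = x, q_end = x + 3L * (aa_e - aa_s))
}

#' Emit truth-derived translated-alignment evidence
#'
#' Stands in for a protein-database search: each query covering at least
#' `min_aa` codons of its gene's CDS receives one sense hit to the true
#' protein, with frame and 0-based half-open coordinates derived from the
#' ground truth.  With probability `noise` a query additionally receives a
#' decoy -- either a hit described as reverse transcriptase or an antisense
#' hit -- to exercise the downstream filters.
#'
#' @param query_spans data.frame: `query_id`, `gene_id`, `q_cds_start`,
#'   `q_cds_end` (CDS span on the query, 0-based half-open; the start may
#'   be negative when the query begins inside the CDS), `aa_total`
#'   (protein length).  Built by [read_query_spans()] or
#'   [transcript_query_spans()].
#' @param proteins named vector of true protein sequences.
#' @param noise decoy probability per query.
#' @param seed RNG seed for e-values and decoys.
#' @param min_aa minimum codons of overlap for a hit to be emitted.
#' @return Evidence data.frame in the internal convention.
#' @export
simulate_evidence <- function(query_spans, proteins, noise = 0, seed = 1L,
                              min_aa = 8L) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(query_spans))) {
    qs <- query_spans[i, ]
    plen <- if (qs$gene_id %in% names(proteins))
      nchar(proteins[[qs$gene_id]]) else NA_integer_
    if (!is.na(plen) && !is.na(qs$q_cds_start)) {
      ov <- cds_overlap_aa(qs$q_cds_start, qs$q_cds_end, qs$q_len, plen)
      aa_s <- ov$aa_s; aa_e <- ov$aa_e
      if (!is.na(aa_e) && aa_e - aa_s >= min_aa) {
        q_start <- ov$q_start
        q_end <- ov$q_end
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = qs$query_id, subject_id = qs$gene_id,
          pct_identity = 100, aln_len = aa_e - aa_s,
          mismatches = 0L, gap_opens = 0L,
          q_start = q_start, q_end = q_end, s_start = aa_s, s_end = aa_e,
          e_value = 10^-runif(1, 30, 80), bitscore = 2 * (aa_e - aa_s),
          frame = (q_start %% 3L) + 1L,
          subject_desc = paste0("protein ", qs$gene_id),
          stringsAsFactors = FALSE)
      }
    }
    if (noise > 0 && runif(1) < noise) {
      decoy_rt <- runif(1) < 0.5
      dlen <- 40L
      q_end <- min(qs$q_len, 3L * dlen)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = qs$query_id,
        subject_id = if (decoy_rt) "RT_decoy" else "AS_decoy",
        pct_identity = 90, aln_len = dlen, mismatches = 4L, gap_opens = 0L,
        q_start = 0L, q_end = q_end, s_start = 0L, s_end = dlen,
        e_value = 10^-runif(1, 10, 25), bitscore = 80,
        frame = if (decoy_rt) 1L else -1L,
        subject_desc = if (decoy_rt) "pol-like reverse transcriptase"
                       else "hypothetical antisense decoy",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(query_id = character(0), subject_id = character(0),
                      pct_identity = numeric(0), aln_len = integer(0),
                      mismatches = integer(0), gap_opens = integer(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      e_value = numeric(0), bitscore = numeric(0),
                      frame = integer(0), subject_desc = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' CDS spans of processed reads, from ground truth
#'
#' @param truth truth table from [simulate_library()].
#' @return `query_spans` data.frame for [simulate_evidence()], two rows per
#'   clone (5' and 3' read).
#' @export
read_query_spans <- function(truth) {
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    do.call(rbind, lapply(c("5p", "3p"), function(end) {
      sp <- query_molecule_span(tr, end)
      data.frame(query_id = paste0(tr$clone_id, "_", end),
                 gene_id = tr$gene_id,
                 q_len = sp[2L] - sp[1L],
                 q_cds_start = if (is.na(tr$mcds_start)) NA_integer_
                               else tr$mcds_start - sp[1L],
                 q_cds_end = if (is.na(tr$mcds_end)) NA_integer_
                             else pmin(tr$mcds_end, sp[2L]) - sp[1L],
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' CDS spans of merged transcripts, from ground truth
#'
#' A merged transcript spans its molecule end to end (the 5' read starts at
#' the molecule start, the 3' read ends at the tail), so the CDS
#' coordinates carry over directly.
#'
#' @param truth truth table from [simulate_library()].
#' @param clone_ids clones that actually merged.
#' @return `query_spans` data.frame for [simulate_evidence()].
#' @export
transcript_query_spans <- function(truth, clone_ids) {
  idx <- match(clone_ids, truth$clone_id)
  data.frame(query_id = clone_ids,
             gene_id = truth$gene_id[idx],
             q_len = truth$mol_len[idx],
             q_cds_start = truth$mcds_start[idx],
             q_cds_end = pmin(truth$mcds_end[idx], truth$mol_len[idx]),
             stringsAsFactors = FALSE)
}
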