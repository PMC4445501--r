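# Artificial repertoire generation from a factorized V(D)J recombination
# model: independent gene choice (V and a joint (D,J) pair), per-segment
# junctional deletion profiles, and non-templated insertions whose lengths
# and nucleotide content follow, respectively, a length distribution and a
# first-order Markov chain.

.nt_alphabet <- c("A", "C", "G", "T")

check_prob <- function(p, what, tol = 1e-9) {
  if (any(p < 0)) stop(what, " has negative entries")
  if (abs(sum(p) - 1) > tol) {
    stop(what, " does not sum to 1 (sum = ", format(sum(p)), ")")
  }
  invisible(p)
}

#' Construct a V(D)J generative model
#'
#' The model factorizes a recombination event into independent draws:
#' V segment from `p_v`; a (D, J) pair jointly from `p_dj`; deletion lengths
#' at the V 3' end, J 5' end and both D ends from per-segment distributions;
#' insertion lengths at the V-D and D-J junctions from `p_ins_len_*`; and
#' inserted nucleotides from first-order Markov chains (`ins_markov_*`,
#' each a list with `initial` (length-4) and `transition` (4x4, rows = from
#' state A/C/G/T)).
#'
#' Deletion distributions are defined over lengths `0..(length(vector)-1)`.
#' When a drawn segment is shorter than the distribution's support, the
#' distribution is renormalized to the feasible lengths (see
#' `deletion_policy`).
#'
#' @param v_segments,d_segments,j_segments named character vectors of segment
#'   nucleotide sequences (names = gene names).
#' @param p_v probability vector over V segments.
#' @param p_dj joint probability matrix, rows = D segments, cols = J segments.
#' @param p_del_v,p_del_j matrices of per-segment deletion-length
#'   distributions: one row per segment, column k = probability of deleting
#'   k-1 nucleotides.
#' @param p_del_d5,p_del_d3 same, per D segment (5' and 3' ends).
#' @param p_ins_len_vd,p_ins_len_dj insertion-length distributions over
#'   `0..L_max`.
#' @param ins_markov_vd,ins_markov_dj Markov chains for inserted nucleotides.
#' @param deletion_policy `"renormalize"` (default): restrict each deletion
#'   distribution to the feasible support and renormalize; `"truncate"`: draw
#'   from the full distribution and clamp to the segment length.
#' @return A validated object of class `"generative_model"`.
#' @seealso [default_model()], [generate_repertoire()]
#' @export
generative_model <- function(v_segments, d_segments, j_segments,
                             p_v, p_dj,
                             p_del_v, p_del_j, p_del_d5, p_del_d3,
                             p_ins_len_vd, p_ins_len_dj,
                             ins_markov_vd, ins_markov_dj,
                             deletion_policy = c("renormalize", "truncate")) {
  deletion_policy <- match.arg(deletion_policy)
  segs <- list(v = v_segments, d = d_segments, j = j_segments)
  for (cls in names(segs)) {
    s <- segs[[cls]]
    if (is.null(names(s)) || any(names(s) == "")) {
      stop(cls, "_segments must be a named character vector")
    }
    if (any(grepl("[^ACGT]", s))) {
      stop(cls, "_segments contain non-ACGT characters")
    }
  }
  check_prob(p_v, "p_v")
  if (length(p_v) != length(v_segments)) stop("p_v length mismatch")
  if (!is.matrix(p_dj) || nrow(p_dj) != length(d_segments) ||
      ncol(p_dj) != length(j_segments)) {
    stop("p_dj must be a |D| x |J| matrix")
  }
  check_prob(as.vector(p_dj), "p_dj")
  check_del <- function(m, segs, what) {
    if (!is.matrix(m) || nrow(m) != length(segs)) {
      stop(what, " must have one row per segment")
    }
    for (i in seq_len(nrow(m))) check_prob(m[i, ], paste0(what, " row ", i))
    invisible(m)
  }
  check_del(p_del_v, v_segments, "p_del_v")
  check_del(p_del_j, j_segments, "p_del_j")
  check_del(p_del_d5, d_segments, "p_del_d5")
  check_del(p_del_d3, d_segments, "p_del_d3")
  check_prob(p_ins_len_vd, "p_ins_len_vd")
  check_prob(p_ins_len_dj, "p_ins_len_dj")
  check_markov <- function(mc, what) {
    if (!is.list(mc) || is.null(mc$initial) || is.null(mc$transition)) {
      stop(what, " must be a list with $initial and $transition")
    }
    check_prob(mc$initial, paste0(what, "$initial"))
    if (!is.matrix(mc$transition) || any(dim(mc$transition) != 4)) {
      stop(what, "$transition must be 4x4")
    }
    for (i in 1:4) check_prob(mc$transition[i, ],
                              paste0(what, "$transition row ", i))
    invisible(mc)
  }
  check_markov(ins_markov_vd, "ins_markov_vd")
  check_markov(ins_markov_dj, "ins_markov_dj")
  # every segment must admit at least one feasible deletion length
  feasible <- function(m, segs) {
    vapply(seq_along(segs), function(i) {
      sup <- min(ncol(m), nchar(segs[[i]]) + 1)
      sum(m[i, seq_len(sup)]) > 0
    }, logical(1))
  }
  if (!all(feasible(p_del_v, v_segments)) ||
      !all(feasible(p_del_j, j_segments)) ||
      !all(feasible(p_del_d5, d_segments))) {
    stop("a deletion distribution puts no mass on any feasible length")
  }
  names(p_v) <- names(v_segments)
  dimnames(p_dj) <- list(names(d_segments), names(j_segments))
  structure(list(
    v_segments = v_segments, d_segments = d_segments, j_segments = j_segments,
    p_v = p_v, p_dj = p_dj,
    p_del_v = p_del_v, p_del_j = p_del_j,
    p_del_d5 = p_del_d5, p_del_d3 = p_del_d3,
    p_ins_len_vd = p_ins_len_vd, p_ins_len_dj = p_ins_len_dj,
    ins_markov_vd = ins_markov_vd, ins_markov_dj = ins_markov_dj,
    deletion_policy = deletion_policy
  ), class = "generative_model")
}

#' @export
print.generative_model <- function(x, ...) {
  cat(sprintf(paste0("V(D)J generative model: %d V, %d D, %d J segments; ",
                     "max insertions %d (VD) / %d (DJ)\n"),
              length(x$v_segments), length(x$d_segments),
              length(x$j_segments),
              length(x$p_ins_len_vd) - 1, length(x$p_ins_len_dj) - 1))
  invisible(x)
}

# Geometric-like pmf on 0..k, renormalized.
geom_pmf <- function(k, rate) {
  p <- rate^(0:k)
  p / sum(p)
}

#' Built-in synthetic generative model
#'
#' A small self-contained parameter set for testing and simulation: 12 V, 2 D
#' and 6 J toy segments with randomly generated sequences, mildly non-uniform
#' gene-choice probabilities, geometric-like deletion and insertion-length
#' profiles and gently biased insertion Markov chains. The parameters are
#' synthetic — convenient, valid, and clearly not inferred from biological
#' data; load a real parameter set with [read_generative_model()] for
#' biologically calibrated simulations.
#'
#' @param seed RNG seed used to generate the toy segment sequences and
#'   probability profiles (default 42); the same seed always yields the same
#'   model.
#' @return A `generative_model`.
#' @export
default_model <- function(seed = 42) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rand_seq <- function(n) {
    paste(sample(.nt_alphabet, n, replace = TRUE), collapse = "")
  }
  n_v <- 12; n_d <- 2; n_j <- 6
  # V segments begin with the canonical TGT (Cys codon) so that most
  # assembled CDR3s start with C, as real junctions do.
  v_segments <- stats::setNames(
    vapply(seq_len(n_v), function(i) paste0("TGT", rand_seq(12)), ""),
    paste0("TRBV", seq_len(n_v), "-1")
  )
  d_segments <- stats::setNames(
    vapply(c(12, 16), rand_seq, ""),
    paste0("TRBD", seq_len(n_d))
  )
  j_segments <- stats::setNames(
    vapply(seq_len(n_j), function(i) paste0(rand_seq(12), "TTT"), ""),
    paste0("TRBJ", rep(1:2, each = 3), "-", rep(1:3, 2))
  )
  p_v <- as.numeric(stats::rgamma(n_v, shape = 2)); p_v <- p_v / sum(p_v)
  p_dj <- matrix(stats::rgamma(n_d * n_j, shape = 2), n_d, n_j)
  p_dj <- p_dj / sum(p_dj)
  del_profile <- function(n_seg, k, rate) {
    t(vapply(seq_len(n_seg), function(i) geom_pmf(k, rate), numeric(k + 1)))
  }
  model <- generative_model(
    v_segments, d_segments, j_segments,
    p_v = p_v, p_dj = p_dj,
    p_del_v = del_profile(n_v, 6, 0.6),
    p_del_j = del_profile(n_j, 6, 0.6),
    p_del_d5 = del_profile(n_d, 5, 0.55),
    p_del_d3 = del_profile(n_d, 5, 0.55),
    p_ins_len_vd = geom_pmf(8, 0.7),
    p_ins_len_dj = geom_pmf(8, 0.7),
    ins_markov_vd = list(
      initial = c(0.2, 0.3, 0.3, 0.2),
      transition = matrix(c(0.25, 0.3, 0.3, 0.15,
                            0.2, 0.3, 0.25, 0.25,
                            0.2, 0.25, 0.3, 0.25,
                            0.15, 0.3, 0.3, 0.25),
                          4, 4, byrow = TRUE,
                          dimnames = list(.nt_alphabet, .nt_alphabet))
    ),
    ins_markov_dj = list(
      initial = c(0.3, 0.2, 0.2, 0.3),
      transition = matrix(c(0.3, 0.25, 0.25, 0.2,
                            0.25, 0.25, 0.25, 0.25,
                            0.25, 0.2, 0.25, 0.3,
                            0.2, 0.25, 0.25, 0.3),
                          4, 4, byrow = TRUE,
                          dimnames = list(.nt_alphabet, .nt_alphabet))
    )
  )
  model
}

# Draw deletion lengths for segment indices `idx` from per-segment profile
# rows, restricted to feasible support `max_len[i]` (renormalize policy) or
# clamped (truncate policy).
sample_deletions <- function(profile, idx, max_len, policy) {
  n <- length(idx)
  out <- integer(n)
  lens <- pmin(ncol(profile) - 1L, max_len)
  # group draws by (segment row, feasible max) for vectorized sampling
  grp <- paste(idx, lens)
  for (g in unique(grp)) {
    sel <- which(grp == g)
    i <- idx[sel[1]]
    lmax <- lens[sel[1]]
    p <- profile[i, seq_len(ncol(profile))]
    if (policy == "renormalize") {
      p <- p[seq_len(lmax + 1)]
      p <- p / sum(p)
      out[sel] <- sample.int(lmax + 1, length(sel), replace = TRUE,
                             prob = p) - 1L
    } else {
      d <- sample.int(length(p), length(sel), replace = TRUE, prob = p) - 1L
      out[sel] <- pmin(d, lmax)
    }
  }
  out
}

# Sample `n` insertion strings with lengths `lens` from a first-order Markov
# chain, all chains advanced in lockstep (one sampling pass per position).
sample_insertions <- function(lens, markov) {
  n <- length(lens)
  out <- character(n)
  if (n == 0) return(out)
  maxL <- max(lens)
  if (maxL == 0) return(out)
  states <- matrix(NA_integer_, nrow = n, ncol = maxL)
  active <- lens >= 1
  states[active, 1] <- sample.int(4, sum(active), replace = TRUE,
                                  prob = markov$initial)
  if (maxL >= 2) {
    for (pos in 2:maxL) {
      active <- lens >= pos
      if (!any(active)) break
      prev <- states[active, pos - 1]
      nxt <- integer(length(prev))
      for (s in 1:4) {
        sel <- prev == s
        if (any(sel)) {
          nxt[sel] <- sample.int(4, sum(sel), replace = TRUE,
                                 prob = markov$transition[s, ])
        }
      }
      states[active, pos] <- nxt
    }
  }
  has <- lens >= 1
  out[has] <- vapply(which(has), function(i) {
    paste(.nt_alphabet[states[i, seq_len(lens[i])]], collapse = "")
  }, character(1))
  out
}

#' Generate an artificial repertoire
#'
#' Draws `n_sequences` independent recombination events from a
#' [generative_model()]: V from `p_v`, a (D, J) pair from `p_dj`, junctional
#' deletions from the per-segment profiles (restricted to feasible lengths),
#' insertion lengths from `p_ins_len_*` and inserted nucleotides from the
#' junction Markov chains. Each event assembles
#' `trimmed-V + VD-insert + trimmed-D + DJ-insert + trimmed-J`; identical
#' assembled sequences are collapsed into clonotypes with summed counts. The
#' output is bit-identical for a fixed `(model, n_sequences, seed)`.
#'
#' @param model a `generative_model`.
#' @param n_sequences number of recombination events to draw (>= 1).
#' @param seed RNG seed (required for reproducibility).
#' @param sample_id sample label of the generated repertoire.
#' @param expansion optional clonal-expansion skew: `NULL` (default, every
#'   draw has count 1 before collapsing) or a positive number `alpha`, in
#'   which case each draw's count is sampled from a discrete power law
#'   `P(c) ~ c^-(alpha+1)` (capped at 10^4), producing the uneven clone sizes
#'   diversity statistics are designed for.
#' @return A `repertoire` whose rows carry CDR3 sequences, translations,
#'   gene names, junction borders and insertion counts, with the per-draw
#'   generation records in `attr(, "records")` (a data frame: chosen genes,
#'   deletion lengths, insertion strings, assembled sequence and borders).
#' @examples
#' r <- generate_repertoire(default_model(), 200, seed = 7)
#' nrow(r) > 1
#' @export
generate_repertoire <- function(model, n_sequences, seed,
                                sample_id = "simulated", expansion = NULL) {
  stopifnot(inherits(model, "generative_model"))
  if (n_sequences < 1) stop("n_sequences must be >= 1")
  if (missing(seed)) stop("a seed is required for reproducible generation")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- as.integer(n_sequences)

  vi <- sample.int(length(model$v_segments), n, replace = TRUE,
                   prob = model$p_v)
  dj_flat <- sample.int(length(model$p_dj), n, replace = TRUE,
                        prob = as.vector(model$p_dj))
  di <- ((dj_flat - 1L) %% nrow(model$p_dj)) + 1L
  ji <- ((dj_flat - 1L) %/% nrow(model$p_dj)) + 1L

  v_len <- nchar(model$v_segments)[vi]
  d_len <- nchar(model$d_segments)[di]
  j_len <- nchar(model$j_segments)[ji]

  del_v <- sample_deletions(model$p_del_v, vi, v_len, model$deletion_policy)
  del_j <- sample_deletions(model$p_del_j, ji, j_len, model$deletion_policy)
  del_d5 <- sample_deletions(model$p_del_d5, di, d_len,
                             model$deletion_policy)
  del_d3 <- sample_deletions(model$p_del_d3, di, d_len - del_d5,
                             model$deletion_policy)

  ins_vd_len <- sample.int(length(model$p_ins_len_vd), n, replace = TRUE,
                           prob = model$p_ins_len_vd) - 1L
  ins_dj_len <- sample.int(length(model$p_ins_len_dj), n, replace = TRUE,
                           prob = model$p_ins_len_dj) - 1L
  ins_vd <- sample_insertions(ins_vd_len, model$ins_markov_vd)
  ins_dj <- sample_insertions(ins_dj_len, model$ins_markov_dj)

  trim_v <- substr(model$v_segments[vi], 1, v_len - del_v)
  trim_d <- substr(model$d_segments[di], del_d5 + 1, d_len - del_d3)
  trim_j <- substr(model$j_segments[ji], del_j + 1, j_len)

  cdr3_nt <- paste0(trim_v, ins_vd, trim_d, ins_dj, trim_j)
  v_end <- nchar(trim_v)
  d_start <- v_end + ins_vd_len
  d_end <- d_start + nchar(trim_d)
  j_start <- d_end + ins_dj_len

  counts <- if (is.null(expansion)) {
    rep(1L, n)
  } else {
    if (!is.numeric(expansion) || expansion <= 0) {
      stop("expansion must be NULL or a positive power-law exponent")
    }
    cmax <- 10000L
    pmf <- (1:cmax)^-(expansion + 1)
    sample.int(cmax, n, replace = TRUE, prob = pmf)
  }

  records <- data.frame(
    v_name = names(model$v_segments)[vi],
    d_name = names(model$d_segments)[di],
    j_name = names(model$j_segments)[ji],
    del_v = del_v, del_j = del_j, del_d5 = del_d5, del_d3 = del_d3,
    ins_vd = ins_vd, ins_dj = ins_dj,
    cdr3_nt = cdr3_nt,
    cdr3_aa = translate_cdr3(cdr3_nt),
    v_end = as.integer(v_end), d_start = as.integer(d_start),
    d_end = as.integer(d_end), j_start = as.integer(j_start),
    count = counts,
    stringsAsFactors = FALSE
  )

  df <- data.frame(
    read_count = counts,
    cdr3_nt = cdr3_nt,
    cdr3_aa = records$cdr3_aa,
    v_gene = records$v_name,
    d_gene = records$d_name,
    j_gene = records$j_name,
    v_end = records$v_end, d_start = records$d_start,
    d_end = records$d_end, j_start = records$j_start,
    vd_insertions = ins_vd_len,
    dj_insertions = ins_dj_len,
    total_insertions = ins_vd_len + ins_dj_len,
    stringsAsFactors = FALSE
  )
  rep_raw <- repertoire(df, sample_id = sample_id)
  out <- collapse_clonotypes(rep_raw, key = "nt")
  attr(out, "records") <- records
  out
}

#' Generation records of a simulated repertoire
#' @param x a repertoire produced by [generate_repertoire()].
#' @return The per-draw record data frame, or `NULL`.
#' @export
generation_records <- function(x) attr(x, "records")

# Standard genetic code, codon -> single-letter amino acid.
.codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' Translate CDR3 nucleotide sequences
#'
#' Standard genetic code translation of complete codons. A trailing partial
#' codon is marked `~`; a codon containing `N` translates to `?`; stop codons
#' translate to `*`. Vectorized.
#'
#' @param nt character vector of DNA sequences over `A,C,G,T,N`.
#' @return Character vector of amino-acid sequences.
#' @examples
#' translate_cdr3("TGTGCCAGCTTT")  # "CASF"
#' translate_cdr3("TGTGC")        # "C~"
#' @export
translate_cdr3 <- function(nt) {
  nt <- toupper(nt)
  if (any(grepl("[^ACGTN]", nt))) {
    stop("invalid nucleotide character (expected A/C/G/T/N)")
  }
  vapply(nt, function(s) {
    L <- nchar(s)
    n_codons <- L %/% 3
    aa <- if (n_codons > 0) {
      codons <- substring(s, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
      res <- .codon_table[codons]
      res[is.na(res)] <- "?"        # codon containing N
      paste(res, collapse = "")
    } else ""
    if (L %% 3 != 0) aa <- paste0(aa, "~")
    aa
  }, character(1), USE.NAMES = FALSE)
}

#' Empirical marginals of generation records
#'
#' Observed frequency tables of every model factor in a set of generation
#' records, aligned to a model's namespaces when one is supplied: V usage,
#' joint (D, J) usage, deletion-length distributions, insertion-length
#' distributions and the insertion dinucleotide transition frequencies.
#' Suitable for total-variation or chi-square comparison against the model
#' parameters.
#'
#' @param records a record data frame from [generate_repertoire()].
#' @param model optional `generative_model` fixing the namespaces and support
#'   sizes.
#' @return A list with `n`, `v` (named frequency vector), `dj` (matrix),
#'   `del_v`, `del_j`, `del_d5`, `del_d3`, `ins_len_vd`, `ins_len_dj`
#'   (frequency vectors over length 0..max), `trans_vd`, `trans_dj`
#'   (4x4 row-normalized transition frequencies, NA rows unobserved).
#' @export
empirical_marginals <- function(records, model = NULL) {
  if (nrow(records) == 0) stop("need at least one record")
  n <- nrow(records)
  freq_over <- function(x, levels) {
    tab <- table(factor(x, levels = levels))
    as.numeric(tab) / n
  }
  v_names <- if (!is.null(model)) names(model$v_segments) else
    sort(unique(records$v_name))
  d_names <- if (!is.null(model)) names(model$d_segments) else
    sort(unique(records$d_name))
  j_names <- if (!is.null(model)) names(model$j_segments) else
    sort(unique(records$j_name))
  len_support <- function(obs, param) {
    if (!is.null(param)) 0:(length(param) - 1) else 0:max(obs)
  }
  dj <- table(factor(records$d_name, levels = d_names),
              factor(records$j_name, levels = j_names)) / n
  trans_freq <- function(strings) {
    m <- matrix(0, 4, 4, dimnames = list(.nt_alphabet, .nt_alphabet))
    for (s in strings[nchar(strings) >= 2]) {
      ch <- strsplit(s, "")[[1]]
      for (i in seq_len(length(ch) - 1)) {
        m[ch[i], ch[i + 1]] <- m[ch[i], ch[i + 1]] + 1
      }
    }
    rs <- rowSums(m)
    sweep(m, 1, ifelse(rs > 0, rs, NA), "/")
  }
  list(
    n = n,
    v = stats::setNames(freq_over(records$v_name, v_names), v_names),
    dj = as.matrix(unclass(dj)),
    del_v = freq_over(records$del_v,
                      len_support(records$del_v,
                                  if (!is.null(model)) model$p_del_v[1, ])),
    del_j = freq_over(records$del_j,
                      len_support(records$del_j,
                                  if (!is.null(model)) model$p_del_j[1, ])),
    del_d5 = freq_over(records$del_d5,
                       len_support(records$del_d5,
                                   if (!is.null(model)) model$p_del_d5[1, ])),
    del_d3 = freq_over(records$del_d3,
                       len_support(records$del_d3,
                                   if (!is.null(model)) model$p_del_d3[1, ])),
    ins_len_vd = freq_over(nchar(records$ins_vd),
                           len_support(nchar(records$ins_vd),
                                       if (!is.null(model))
                                         model$p_ins_len_vd)),
    ins_len_dj = freq_over(nchar(records$ins_dj),
                           len_support(nchar(records$ins_dj),
                                       if (!is.null(model))
                                         model$p_ins_len_dj)),
    trans_vd = trans_freq(records$ins_vd),
    trans_dj = trans_freq(records$ins_dj)
  )
}

#' Write a generative model to JSON
#'
#' Serializes all model parameters (segment sequences, gene-choice, deletion,
#' insertion and Markov-chain probabilities) to a JSON file readable by
#' [read_generative_model()].
#'
#' @param model a `generative_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_generative_model <- function(model, path) {
  stopifnot(inherits(model, "generative_model"))
  obj <- list(
    v_segments = as.list(model$v_segments),
    d_segments = as.list(model$d_segments),
    j_segments = as.list(model$j_segments),
    p_v = unname(model$p_v),
    p_dj = unname(model$p_dj),
    p_del_v = model$p_del_v, p_del_j = model$p_del_j,
    p_del_d5 = model$p_del_d5, p_del_d3 = model$p_del_d3,
    p_ins_len_vd = model$p_ins_len_vd, p_ins_len_dj = model$p_ins_len_dj,
    ins_markov_vd = list(initial = model$ins_markov_vd$initial,
                         transition = unname(model$ins_markov_vd$transition)),
    ins_markov_dj = list(initial = model$ins_markov_dj$initial,
                         transition = unname(model$ins_markov_dj$transition)),
    deletion_policy = model$deletion_policy
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a generative model from JSON
#'
#' @param path JSON file written by [write_generative_model()] (or matching
#'   its schema).
#' @return A validated `generative_model`.
#' @export
read_generative_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m) if (is.matrix(m)) m else as.matrix(m)
  generative_model(
    v_segments = unlist(obj$v_segments),
    d_segments = unlist(obj$d_segments),
    j_segments = unlist(obj$j_segments),
    p_v = obj$p_v,
    p_dj = as_mat(obj$p_dj),
    p_del_v = as_mat(obj$p_del_v), p_del_j = as_mat(obj$p_del_j),
    p_del_d5 = as_mat(obj$p_del_d5), p_del_d3 = as_mat(obj$p_del_d3),
    p_ins_len_vd = obj$p_ins_len_vd, p_ins_len_dj = obj$p_ins_len_dj,
    ins_markov_vd = list(initial = obj$ins_markov_vd$initial,
                         transition = as_mat(obj$ins_markov_vd$transition)),
    ins_markov_dj = list(initial = obj$ins_markov_dj$initial,
                         transition = as_mat(obj$ins_markov_dj$transition)),
    deletion_policy = if (!is.null(obj$deletion_policy)) {
      obj$deletion_policy
    } else "renormalize"
  )
}
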