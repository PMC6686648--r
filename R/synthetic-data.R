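# Seeded-deterministic RNG scope: evaluates `expr` under `seed` and restores
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n, len) {
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# The 61 sense codons; gene bodies are built from them so that the
# full-length transcript carries an uninterrupted frame-1 reading frame,
# as a real protein-coding transcript would.
sense_codons <- function() {
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1, paste0,
                      collapse = "")
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
}

# A coding-like DNA string of total length `total`, split at `len` cumsum
# boundaries into exons.
random_coding_exons <- function(len) {
  total <- sum(len)
  s <- paste(sample(sense_codons(), ceiling(total / 3), replace = TRUE),
             collapse = "")
  s <- substr(s, 1L, total)
  ends <- cumsum(len)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  substring(s, starts, ends)
}

#' Generate toy gene models
#'
#' Each gene has 2-4 exons of 50-300 bp and 1-3 isoforms; the first isoform
#' always chains all exons (the full-length transcript), additional isoforms
#' are ordered exon subsets, mimicking the exon / exon-group structure that
#' splicing-graph nodes represent.  Gene bodies are assembled from sense
#' codons, so the full-length transcript reads through in frame 1 like a
#' protein-coding sequence (see [gene_proteins()]).  Exon sequences are
#' globally distinct across genes.
#'
#' @param n_genes Number of genes (>= 1).
#' @param rng_seed Integer seed; output is byte-identical for equal seeds.
#' @return List of gene models; each is a list with `gene_id`, `exons`
#'   (character vector), `isoforms` (list of integer vectors of exon
#'   indices), and `isoform_seqs` (spliced sequences).
#' @export
generate_gene_models <- function(n_genes, rng_seed = 1L) {
  if (length(n_genes) != 1L || is.na(n_genes) || n_genes < 1) {
    stop("n_genes must be >= 1")
  }
  with_seed(rng_seed, {
    seen <- character(0)
    lapply(seq_len(n_genes), function(i) {
      n_ex <- sample(2:4, 1)
      exons <- random_coding_exons(sample(50:300, n_ex, replace = TRUE))
      while (any(exons %in% seen) || anyDuplicated(exons)) {
        exons <- random_coding_exons(sample(50:300, n_ex, replace = TRUE))
      }
      seen <<- c(seen, exons)
      n_iso <- sample(1:3, 1)
      isoforms <- list(seq_len(n_ex))
      if (n_iso > 1) {
        for (j in 2:n_iso) {
          sz <- sample(seq_len(n_ex), 1)
          isoforms[[j]] <- sort(sample(seq_len(n_ex), sz))
        }
        isoforms <- unique(isoforms)
      }
      list(
        gene_id = sprintf("gene%03d", i),
        exons = exons,
        isoforms = isoforms,
        isoform_seqs = vapply(isoforms, function(ix) {
          paste(exons[ix], collapse = "")
        }, character(1))
      )
    })
  })
}

#' The twelve-library sibling-pair design
#'
#' Six sibling pairs (three female, three male), each pair contributing one
#' actively predating and one nonpredating larva, sequenced as one library
#' each.  Size factors default to a seeded log-uniform draw in `[0.5, 2]`,
#' emulating library-depth variation.
#'
#' @param size_factors Optional numeric vector of 12 positive size factors
#'   (predator/nonpredator of pair 1, then pair 2, ...).
#' @param rng_seed Seed for the default size-factor draw.
#' @return data.frame with columns `library_id`, `pair_id`, `sex`,
#'   `behavior`, `size_factor`.
#' @export
library_design <- function(size_factors = NULL, rng_seed = 1L) {
  des <- data.frame(
    library_id = sprintf("%s%d", rep(c("P", "N"), 6), rep(1:6, each = 2)),
    pair_id = rep(1:6, each = 2),
    sex = rep(c("female", "male"), each = 6),
    behavior = rep(c("predator", "nonpredator"), 6),
    stringsAsFactors = FALSE
  )
  if (is.null(size_factors)) {
    size_factors <- with_seed(rng_seed, exp(stats::runif(12, log(0.5), log(2))))
  }
  stopifnot(length(size_factors) == 12L, all(size_factors > 0))
  des$size_factor <- size_factors
  des
}

validate_design <- function(design) {
  stopifnot(all(c("library_id", "pair_id", "behavior") %in% names(design)))
  if (!all(design$behavior %in% c("predator", "nonpredator"))) {
    stop("behavior must be predator/nonpredator")
  }
  tab <- table(design$pair_id, design$behavior)
  if (!all(tab == 1L)) {
    stop("each pair must have exactly one predator and one nonpredator library")
  }
  invisible(design)
}

#' Build a ground-truth manifest of expression effects
#'
#' Assigns each gene a baseline expected count, a behavior (predator vs
#' nonpredator) log2 fold change, and a sibling-pair random-effect standard
#' deviation on the log2 scale.  `direction` records the sign of the
#' behavior effect (`none` for null genes).
#'
#' @param gene_ids Character vector of gene ids.
#' @param baseline_mean Baseline expected count at size factor 1 (recycled).
#' @param behavior_log2fc Log2 fold change, predator over nonpredator
#'   (recycled; 0 for null genes).
#' @param pair_effect_sd Nonnegative SD of the per-pair log2 offset
#'   (recycled).
#' @return data.frame manifest.
#' @export
truth_manifest <- function(gene_ids, baseline_mean = 100,
                           behavior_log2fc = 0, pair_effect_sd = 0) {
  stopifnot(all(pair_effect_sd >= 0), all(baseline_mean >= 0))
  data.frame(
    gene_id = gene_ids,
    baseline_mean = rep_len(baseline_mean, length(gene_ids)),
    behavior_log2fc = rep_len(behavior_log2fc, length(gene_ids)),
    pair_effect_sd = rep_len(pair_effect_sd, length(gene_ids)),
    direction = ifelse(rep_len(behavior_log2fc, length(gene_ids)) > 0, "predator",
                ifelse(rep_len(behavior_log2fc, length(gene_ids)) < 0,
                       "nonpredator", "none")),
    stringsAsFactors = FALSE
  )
}

#' Simulate a gene-by-library negative-binomial count table
#'
#' Counts for gene g in library l are drawn NB with mean
#' `size_factor_l * baseline_g * 2^(lfc_g * I[predator_l]) *
#' 2^(pair_offset_{g, pair_l})`, where the per-gene, per-pair offsets are
#' Normal(0, pair_effect_sd_g) on the log2 scale (shared by the two
#' siblings of a pair, emulating a common rearing environment), and
#' `variance = mu + dispersion * mu^2`.
#'
#' @param manifest data.frame from [truth_manifest()].
#' @param design data.frame from [library_design()].
#' @param dispersion NB dispersion alpha (> 0).
#' @param rng_seed Integer seed.
#' @return Integer matrix, genes x libraries.
#' @export
simulate_counts <- function(manifest, design = library_design(),
                            dispersion = 0.05, rng_seed = 1L) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  validate_design(design)
  with_seed(rng_seed, {
    n_g <- nrow(manifest)
    pairs <- sort(unique(design$pair_id))
    offsets <- matrix(stats::rnorm(n_g * length(pairs)), n_g) *
      manifest$pair_effect_sd
    colnames(offsets) <- as.character(pairs)
    pred <- as.integer(design$behavior == "predator")
    mu <- outer(manifest$baseline_mean, design$size_factor) *
      2^(outer(manifest$behavior_log2fc, pred)) *
      2^(offsets[, as.character(design$pair_id), drop = FALSE])
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
      nrow = n_g, dimnames = list(manifest$gene_id, design$library_id)
    )
    counts[manifest$baseline_mean == 0, ] <- 0L
    storage.mode(counts) <- "integer"
    counts
  })
}

#' The Illumina adapter/contaminant sequences screened during read QC
#'
#' The four TruSeq-style 50-mers screened before assembly; [adapter_set()]
#' closes them under reverse complement.
#'
#' @return Character vector of four 50-mers.
#' @export
illumina_adapters <- function() {
  c("GATCGGAAGAGCACACGTCTGAACTCCAGTCACTGACCAATCTCGTATGC",
    "GATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTAGATCTCGGTGGTCGCCG",
    "GATCGGAAGAGCACACGTCTGAACTCCAGTCACACAGTGATCTCGTATGC",
    "GATCGGAAGAGCACACGTCTGAACTCCAGTCACTAGCTTATCTCGTATGC")
}

#' Simulate paired-end reads from gene models and a count table
#'
#' One fragment per count unit: for each gene and library, `counts[g, l]`
#' fragments are drawn from a uniformly chosen isoform of gene g (among
#' isoforms long enough to hold a fragment), at a uniform start position,
#' with fragment length fixed at `read_length`.  Mate 1 is the fragment and
#' mate 2 its reverse complement, with the two roles swapped with
#' probability 0.5 (unstranded protocol).  Substitution errors are applied
#' per base at `error_rate`; a fraction `adapter_fraction` of reads has one
#' of the four [illumina_adapters()] overwritten into it at a random
#' offset.  Qualities are constant Q40 (`"I"`).
#'
#' @param models Gene models from [generate_gene_models()].
#' @param counts Gene-by-library matrix from [simulate_counts()].
#' @param read_length Read length in bp (>= 20).
#' @param error_rate Per-base substitution probability.
#' @param adapter_fraction Fraction of reads carrying an adapter insertion.
#' @param rng_seed Integer seed.
#' @param out_dir If non-NULL, write `<library>_1.fastq` / `<library>_2.fastq`
#'   there and return file paths in the result.
#' @return Named list per library with data.frames `mate1`, `mate2`
#'   (columns `id`, `seq`, `qual`) and, with `out_dir`, `files`.
#' @export
simulate_reads <- function(models, counts, read_length = 100,
                           error_rate = 0, adapter_fraction = 0,
                           rng_seed = 1L, out_dir = NULL) {
  if (read_length < 20) stop("read_length must be >= 20")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (adapter_fraction < 0 || adapter_fraction > 1) {
    stop("adapter_fraction must be in [0, 1]")
  }
  gene_ids <- vapply(models, `[[`, character(1), "gene_id")
  stopifnot(all(rownames(counts) %in% gene_ids))
  eligible <- lapply(models, function(m) {
    which(nchar(m$isoform_seqs) >= read_length)
  })
  names(eligible) <- gene_ids
  if (sum(counts) > 0 && all(lengths(eligible) == 0L)) {
    stop("no reads producible: read_length exceeds every isoform length")
  }
  no_iso <- rownames(counts)[lengths(eligible[rownames(counts)]) == 0L &
                             rowSums(counts) > 0]
  if (length(no_iso) > 0L) {
    warning(sprintf("%d gene(s) have no isoform >= read_length; their counts produce no reads",
                    length(no_iso)))
  }
  with_seed(rng_seed, {
    out <- lapply(colnames(counts), function(lib) {
      frag_gene <- rep(rownames(counts), counts[, lib])
      frag_gene <- frag_gene[lengths(eligible[frag_gene]) > 0L]
      n <- length(frag_gene)
      if (n == 0L) {
        empty <- data.frame(id = character(0), seq = character(0),
                            qual = character(0), stringsAsFactors = FALSE)
        return(list(mate1 = empty, mate2 = empty))
      }
      iso <- vapply(frag_gene, function(g) {
        e <- eligible[[g]]
        if (length(e) == 1L) e else sample(e, 1)
      }, integer(1))
      mi <- match(frag_gene, gene_ids)
      iso_seq <- mapply(function(m, j) m$isoform_seqs[j], models[mi], iso)
      start <- vapply(nchar(iso_seq) - read_length + 1L, function(w) {
        if (w == 1L) 1L else sample.int(w, 1)
      }, integer(1))
      frag <- substr(iso_seq, start, start + read_length - 1L)
      frag <- add_substitution_errors(frag, error_rate)
      frag <- insert_adapters(frag, adapter_fraction)
      m1 <- frag
      m2 <- revcomp(frag)
      flip <- stats::runif(n) < 0.5
      tmp <- m1[flip]; m1[flip] <- m2[flip]; m2[flip] <- tmp
      qual <- strrep("I", nchar(m1))
      base <- sprintf("%s:%s:%d", lib, frag_gene, seq_len(n))
      list(
        mate1 = data.frame(id = paste0(base, "/1"), seq = m1, qual = qual,
                           stringsAsFactors = FALSE, row.names = NULL),
        mate2 = data.frame(id = paste0(base, "/2"), seq = m2, qual = qual,
                           stringsAsFactors = FALSE, row.names = NULL)
      )
    })
    names(out) <- colnames(counts)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (lib in names(out)) {
        f1 <- file.path(out_dir, paste0(lib, "_1.fastq"))
        f2 <- file.path(out_dir, paste0(lib, "_2.fastq"))
        write_fastq(out[[lib]]$mate1, f1)
        write_fastq(out[[lib]]$mate2, f2)
        out[[lib]]$files <- c(f1, f2)
      }
    }
    out
  })
}

# Per-base substitutions at rate `rate`; each error replaces the base with a
# uniformly chosen different base.
add_substitution_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  L <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), L, rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(L[i], n_err[i])
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(bases, b), 1),
                      character(1))
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# Overwrite an adapter into a fraction of reads.  If the read is shorter
# than the adapter, the adapter's prefix fills the whole read.
insert_adapters <- function(seqs, fraction) {
  if (fraction <= 0 || length(seqs) == 0L) return(seqs)
  ad <- illumina_adapters()
  hit <- which(stats::runif(length(seqs)) < fraction)
  for (i in hit) {
    a <- ad[[sample.int(length(ad), 1)]]
    L <- nchar(seqs[i]); al <- nchar(a)
    if (L <= al) {
      seqs[i] <- substr(a, 1L, L)
    } else {
      off <- sample.int(L - al + 1L, 1)
      substr(seqs[i], off, off + al - 1L) <- a
    }
  }
  seqs
}

#' Derive a toy proteome from gene models
#'
#' Translates the full-length isoform of each gene in frame 1 and keeps the
#' longest stop-free segment, if it reaches `min_aa` residues.  Used as the
#' closed-world protein database for [mini_translated_search()].
#'
#' @param models Gene models from [generate_gene_models()].
#' @param min_aa Minimum protein length to keep.
#' @return Named character vector of protein sequences (names = gene ids).
#' @export
gene_proteins <- function(models, min_aa = 20L) {
  out <- vapply(models, function(m) {
    s <- m$isoform_seqs[1]
    s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(s), if.fuzzy.codon = "X"
    ))
    segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
    if (length(segs) == 0L) return("")
    segs[which.max(nchar(segs))]
  }, character(1))
  names(out) <- vapply(models, `[[`, character(1), "gene_id")
  out[nchar(out) >= min_aa]
}
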