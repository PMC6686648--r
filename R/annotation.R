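#' Read tabular homology hits (12-column "outfmt 6" dialect)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore.
#'
#' @param path Path to a tab-separated hit file without header.
#' @return data.frame with the 12 standard columns.
#' @examples
#' hits <- read_blast_tab(system.file("extdata", "example_hits.tsv",
#'                                    package = "facpred"))
#' best_hit_filter(hits)
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) != 12L) stop("expected 12 tab-separated columns")
  names(x) <- cols
  x
}

#' Retain the top homology hit per query under an E-value ceiling
#'
#' Per query the hit with minimal E-value is retained (ties broken by
#' maximal bitscore, then lexicographically smallest subject id); the query
#' is annotated only if that hit's E-value is at or below `max_evalue`,
#' otherwise it is reported unannotated (`gene_id = NA`).
#'
#' @param hits data.frame with at least `qseqid`, `sseqid`, `evalue`,
#'   `bitscore`.
#' @param max_evalue Annotation threshold (default 1e-7).
#' @return data.frame with `node_id`, `gene_id` (NA if unannotated),
#'   `evalue` of the retained hit.
#' @export
best_hit_filter <- function(hits, max_evalue = 1e-7) {
  need <- c("qseqid", "sseqid", "evalue", "bitscore")
  stopifnot(all(need %in% names(hits)))
  if (nrow(hits) == 0L) {
    return(data.frame(node_id = character(0), gene_id = character(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  }
  if (any(hits$evalue < 0)) stop("malformed input: negative E-value")
  o <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid)
  h <- hits[o, ]
  top <- h[!duplicated(h$qseqid), ]
  data.frame(
    node_id = top$qseqid,
    gene_id = ifelse(top$evalue <= max_evalue, top$sseqid, NA_character_),
    evalue = top$evalue,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# Ungapped Karlin-Altschul constants for BLOSUM62; used to convert local
# alignment scores S to E = K * m * n * exp(-lambda * S).
KA_LAMBDA <- 0.3176
KA_K <- 0.134

#' Miniature six-frame translated homology search
#'
#' Closed-world stand-in for a translated nucleotide-vs-protein database
#' search, for synthetic pipelines only.  Each node sequence is translated
#' in all six reading frames (stops become `*`), locally aligned
#' (Smith-Waterman, BLOSUM62, gap open 11 / extend 1) against every
#' protein, and the score is converted to an E-value with the ungapped
#' Karlin-Altschul constants for BLOSUM62 (lambda = 0.3176, K = 0.134):
#' `E = K * m * n * exp(-lambda * S)`, m and n the frame and protein
#' lengths.  Hits with `E > ceiling` are omitted.  Deterministic.
#'
#' @param nodes Named character vector of node DNA sequences (nodes shorter
#'   than 3 bp are skipped with a warning).
#' @param proteins Named character vector of protein sequences.
#' @param evalue_ceiling Hits with larger E are not reported (default 10).
#' @return data.frame with `qseqid`, `sseqid`, `frame`, `score`,
#'   `bitscore`, `evalue`.
#' @export
mini_translated_search <- function(nodes, proteins, evalue_ceiling = 10) {
  if (length(proteins) == 0L) {
    return(data.frame(qseqid = character(0), sseqid = character(0),
                      frame = integer(0), score = numeric(0),
                      bitscore = numeric(0), evalue = numeric(0)))
  }
  stopifnot(!is.null(names(nodes)), !is.null(names(proteins)))
  short <- nchar(nodes) < 3L
  if (any(short)) {
    warning(sprintf("skipping %d node(s) shorter than 3 bp", sum(short)))
    nodes <- nodes[!short]
  }
  frames <- six_frame_translations(nodes)
  if (nrow(frames) == 0L) {
    return(data.frame(qseqid = character(0), sseqid = character(0),
                      frame = integer(0), score = numeric(0),
                      bitscore = numeric(0), evalue = numeric(0)))
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  pat <- Biostrings::AAStringSet(frames$aa)
  out <- vector("list", length(proteins))
  for (j in seq_along(proteins)) {
    subj <- Biostrings::AAString(proteins[[j]])
    sc <- Biostrings::pairwiseAlignment(
      pat, subj, type = "local", substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
    )
    ev <- KA_K * nchar(frames$aa) * nchar(proteins[[j]]) * exp(-KA_LAMBDA * sc)
    out[[j]] <- data.frame(
      qseqid = frames$node, sseqid = names(proteins)[j],
      frame = frames$frame, score = sc,
      bitscore = (KA_LAMBDA * sc - log(KA_K)) / log(2),
      evalue = ev, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[res$evalue <= evalue_ceiling, , drop = FALSE]
  # one row per (node, protein): best frame
  o <- order(res$qseqid, res$sseqid, res$evalue, res$frame)
  res <- res[o, ]
  res <- res[!duplicated(res[c("qseqid", "sseqid")]), ]
  rownames(res) <- NULL
  res
}

six_frame_translations <- function(nodes) {
  rows <- list()
  rc <- revcomp(nodes)
  for (f in 1:3) {
    for (strand in c(1L, -1L)) {
      s <- if (strand == 1L) nodes else rc
      s <- substr(s, f, nchar(s))
      s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
      ok <- nchar(s) >= 3L
      if (!any(ok)) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(s[ok]), if.fuzzy.codon = "X"
      ))
      rows[[length(rows) + 1L]] <- data.frame(
        node = names(nodes)[ok], frame = strand * f, aa = aa,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(node = character(0), frame = integer(0),
                      aa = character(0)))
  }
  do.call(rbind, rows)
}

#' Annotate assembly nodes by their true source gene
#'
#' Ground-truth annotation for synthetic data: a node is assigned to a gene
#' iff the node sequence (or its reverse complement) is an exact substring
#' of one of the gene's isoform sequences, and only one gene matches.
#'
#' @param assembly A `"splicing_assembly"`.
#' @param models Gene models from [generate_gene_models()].
#' @return data.frame with `node_id`, `gene_id` (NA when no or ambiguous
#'   match).
#' @export
annotate_nodes_by_truth <- function(assembly, models) {
  seqs <- assembly$nodes$sequence
  rcs <- revcomp(seqs)
  gene <- vapply(seq_along(seqs), function(i) {
    hits <- vapply(models, function(m) {
      any(vapply(m$isoform_seqs, function(iso) {
        grepl(seqs[i], iso, fixed = TRUE) || grepl(rcs[i], iso, fixed = TRUE)
      }, logical(1)))
    }, logical(1))
    if (sum(hits) == 1L) models[[which(hits)]]$gene_id else NA_character_
  }, character(1))
  data.frame(node_id = assembly$nodes$node_id, gene_id = gene,
             stringsAsFactors = FALSE)
}

#' Gene sets of splicing graphs
#'
#' The gene set of a splicing graph (connected component) is the union of
#' its nodes' annotations; graphs whose nodes are all unannotated get an
#' empty set, and graphs may align to multiple genes.
#'
#' @param assembly A `"splicing_assembly"`.
#' @param annotations data.frame with `node_id`, `gene_id` (NA =
#'   unannotated), as from [best_hit_filter()].
#' @return Named list: component id (as character) to character vector of
#'   gene ids (possibly empty).
#' @export
graph_annotation <- function(assembly, annotations) {
  if (!all(annotations$node_id %in% assembly$nodes$node_id)) {
    stop("annotations refer to unknown node ids")
  }
  comp <- assembly$nodes$component_id[match(annotations$node_id,
                                            assembly$nodes$node_id)]
  out <- lapply(split(annotations$gene_id, comp), function(g) {
    sort(unique(g[!is.na(g)]))
  })
  # components with no annotated row at all
  missing <- setdiff(unique(assembly$nodes$component_id), as.integer(names(out)))
  for (m in missing) out[[as.character(m)]] <- character(0)
  out[order(as.integer(names(out)))]
}

#' Annotate an assembly with the miniature translated search
#'
#' Runs [mini_translated_search()] of the assembly's node sequences against
#' a protein set and keeps the top hit per node at the E-value threshold.
#'
#' @param assembly A `"splicing_assembly"`.
#' @param proteins Named character vector of proteins.
#' @param max_evalue Annotation threshold (default 1e-7).
#' @return data.frame as from [best_hit_filter()], one row per node (nodes
#'   without any reported hit are unannotated).
#' @export
annotate_assembly <- function(assembly, proteins, max_evalue = 1e-7) {
  seqs <- assembly$nodes$sequence
  names(seqs) <- assembly$nodes$node_id
  hits <- mini_translated_search(seqs, proteins)
  ann <- best_hit_filter(hits, max_evalue)
  miss <- setdiff(assembly$nodes$node_id, ann$node_id)
  if (length(miss) > 0L) {
    ann <- rbind(ann, data.frame(node_id = miss, gene_id = NA_character_,
                                 evalue = NA_real_, stringsAsFactors = FALSE))
  }
  ann[match(assembly$nodes$node_id, ann$node_id), , drop = FALSE]
}
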