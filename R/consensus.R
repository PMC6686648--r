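#' Tally differential-expression calls to gene level across assemblies
#'
#' A gene counts as "detected in assembly A" iff at least one node
#' annotated to it has a non-`ns` class in A; multiple detecting splicing
#' graphs within one assembly still count once for that assembly.  The
#' consensus direction is `up-in-predator` if every detection is
#' predator-biased, `down-in-predator` if every detection is
#' nonpredator-biased, else `mixed`.  Differentially expressed nodes
#' without annotation are reported separately, keyed by assembly, component
#' and a node-sequence signature so they can be cross-referenced after a
#' later annotation round.
#'
#' @param per_assembly Named list (unique assembly names, `"k_c"`); each
#'   element a list with `results` (data.frame from [nested_de()]),
#'   `annotations` (data.frame `node_id`, `gene_id`), and optionally
#'   `components` (data.frame `node_id`, `component_id`; used for
#'   graph-level tallies) and `sequences` (data.frame `node_id`,
#'   `sequence`; used to sign unannotated nodes).
#' @return List with `genes` (data.frame: `gene_id`,
#'   `n_assemblies_detected`, `direction`, `assemblies`,
#'   `n_graphs_per_assembly`) and `unannotated` (data.frame: `assembly`,
#'   `component_id`, `node_id`, `signature`, `class`).
#' @export
tally_genes <- function(per_assembly) {
  if (is.null(names(per_assembly)) || anyDuplicated(names(per_assembly))) {
    stop("per-assembly results must be uniquely named")
  }
  det <- list(); unann <- list()
  for (a in names(per_assembly)) {
    entry <- per_assembly[[a]]
    res <- entry$results
    de <- res[res$class != "ns", , drop = FALSE]
    if (nrow(de) == 0L) next
    ann <- entry$annotations
    gid <- ann$gene_id[match(de$node_id, ann$node_id)]
    comp <- if (!is.null(entry$components)) {
      entry$components$component_id[match(de$node_id, entry$components$node_id)]
    } else rep(NA_integer_, nrow(de))
    hit <- !is.na(gid)
    if (any(hit)) {
      det[[a]] <- data.frame(
        assembly = a, gene_id = gid[hit], class = de$class[hit],
        component_id = comp[hit], stringsAsFactors = FALSE
      )
    }
    if (any(!hit)) {
      sig <- if (!is.null(entry$sequences)) {
        seqs <- entry$sequences$sequence[match(de$node_id[!hit],
                                               entry$sequences$node_id)]
        substr(vapply(seqs, function(s) {
          # cheap deterministic signature: length + first/last 16 bases
          sprintf("%d:%s:%s", nchar(s), substr(s, 1, 16),
                  substr(s, nchar(s) - 15, nchar(s)))
        }, character(1)), 1, 64)
      } else NA_character_
      unann[[a]] <- data.frame(
        assembly = a, component_id = comp[!hit], node_id = de$node_id[!hit],
        signature = sig, class = de$class[!hit], stringsAsFactors = FALSE
      )
    }
  }
  if (length(det) == 0L) {
    genes <- data.frame(gene_id = character(0),
                        n_assemblies_detected = integer(0),
                        direction = character(0), assemblies = character(0),
                        stringsAsFactors = FALSE)
    genes$n_graphs_per_assembly <- list()
  } else {
    d <- do.call(rbind, det)
    genes <- do.call(rbind, lapply(split(d, d$gene_id), function(g) {
      asms <- sort(unique(g$assembly))
      dirs <- unique(g$class)
      direction <- if (identical(dirs, "predator-biased")) "up-in-predator"
        else if (identical(dirs, "nonpredator-biased")) "down-in-predator"
        else "mixed"
      out <- data.frame(
        gene_id = g$gene_id[1],
        n_assemblies_detected = length(asms),
        direction = direction,
        assemblies = paste(asms, collapse = ";"),
        stringsAsFactors = FALSE
      )
      out$n_graphs_per_assembly <- list(vapply(split(g, g$assembly), function(x) {
        length(unique(x$component_id))
      }, integer(1)))
      out
    }))
    genes <- genes[order(-genes$n_assemblies_detected, genes$gene_id), ]
    rownames(genes) <- NULL
  }
  list(
    genes = genes,
    unannotated = if (length(unann) > 0L) {
      u <- do.call(rbind, unann); rownames(u) <- NULL; u
    } else {
      data.frame(assembly = character(0), component_id = integer(0),
                 node_id = character(0), signature = character(0),
                 class = character(0), stringsAsFactors = FALSE)
    }
  )
}

#' Tiered detection-frequency report
#'
#' Tier 1: genes detected in at least `headline_min` assemblies; tier 2:
#' in at least `secondary_min` but fewer than `headline_min`; tier 3: the
#' rest.  Within a tier genes sort by detection count (descending) then
#' gene id.
#'
#' @param records `genes` data.frame from [tally_genes()].
#' @param headline_min,secondary_min Tier thresholds (headline >=
#'   secondary >= 1).
#' @return The records with a `tier` column, sorted.
#' @export
frequency_report <- function(records, headline_min = 10L, secondary_min = 7L) {
  if (headline_min < secondary_min || secondary_min < 1L) {
    stop("need headline_min >= secondary_min >= 1")
  }
  n <- records$n_assemblies_detected
  records$tier <- ifelse(n >= headline_min, 1L,
                  ifelse(n >= secondary_min, 2L, 3L))
  records <- records[order(records$tier, -records$n_assemblies_detected,
                           records$gene_id), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Per-assembly and average differential-expression counts
#'
#' Counts differentially expressed nodes and splicing graphs per assembly
#' and summarizes across assemblies (mean / max / min), mirroring how a
#' parameter sweep is reported.
#'
#' @param per_assembly As in [tally_genes()] (needs `components` for graph
#'   counts).
#' @return List with `per_assembly` (data.frame: `assembly`, `n_de_nodes`,
#'   `n_de_graphs`) and `summary` (data.frame: statistic, nodes, graphs).
#' @export
summarize_assembly_stats <- function(per_assembly) {
  if (length(per_assembly) == 0L) stop("need at least one assembly")
  rows <- lapply(names(per_assembly), function(a) {
    entry <- per_assembly[[a]]
    de <- entry$results[entry$results$class != "ns", , drop = FALSE]
    n_graphs <- if (!is.null(entry$components) && nrow(de) > 0L) {
      comp <- entry$components$component_id[match(de$node_id,
                                                  entry$components$node_id)]
      length(unique(comp))
    } else if (nrow(de) == 0L) 0L else NA_integer_
    data.frame(assembly = a, n_de_nodes = nrow(de), n_de_graphs = n_graphs,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  s <- function(x, f) if (all(is.na(x))) NA_real_ else f(x, na.rm = TRUE)
  summary <- data.frame(
    statistic = c("mean", "max", "min"),
    n_de_nodes = c(mean(per$n_de_nodes), max(per$n_de_nodes),
                   min(per$n_de_nodes)),
    n_de_graphs = c(s(per$n_de_graphs, function(x, ...) mean(x, ...)),
                    s(per$n_de_graphs, max), s(per$n_de_graphs, min))
  )
  list(per_assembly = per, summary = summary)
}
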