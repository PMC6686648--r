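#' Assembly parameter setting
#'
#' A splicing-graph assembly is parameterized by the k-mer length `k` and the
#' k-mer coverage cutoff `c`: only k-mers whose (canonical, strand-collapsed)
#' count reaches `c` enter the graph.  Settings are named `"k_c"`, e.g.
#' `"25_50"`.  `k` must be odd, which guarantees no k-mer equals its own
#' reverse complement.
#'
#' @param k Odd integer k-mer length (>= 3; typical assemblies use 15-99).
#' @param c Coverage cutoff, integer >= 1 (k-mers with canonical count >= c
#'   are kept).
#' @return List with `k`, `c`, `name`, class `"assembly_params"`.
#' @export
assembly_params <- function(k, c) {
  k <- as.integer(k); c <- as.integer(c)
  if (is.na(k) || k < 3L || k %% 2L == 0L) stop("k must be an odd integer >= 3")
  if (is.na(c) || c < 1L) stop("c must be an integer >= 1")
  structure(list(k = k, c = c, name = paste0(k, "_", c)),
            class = "assembly_params")
}

#' Default parameter sweep grid
#'
#' 24 settings: k in {25, 31, 41, 49} crossed with coverage cutoffs
#' c in {2, 5, 10, 25, 50, 100}.
#'
#' @return List of [assembly_params()] settings.
#' @export
default_assembly_grid <- function() {
  grid <- expand.grid(k = c(25L, 31L, 41L, 49L),
                      c = c(2L, 5L, 10L, 25L, 50L, 100L))
  grid <- grid[order(grid$k, grid$c), ]
  unname(Map(assembly_params, grid$k, grid$c))
}

#' Canonical form of k-mer strings
#'
#' The canonical form is the lexicographically smaller of a k-mer and its
#' reverse complement; strand-collapsed counting and coverage cutoffs use it.
#'
#' @param kmers Character vector of k-mers (no N).
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmer <- function(kmers) {
  if (length(kmers) == 0L) return(character(0))
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

# All length-k substrings of `reads`, in read orientation.
extract_kmers <- function(reads, k) {
  reads <- reads[nchar(reads) >= k]
  if (length(reads) == 0L) return(character(0))
  L <- nchar(reads)
  nwin <- max(L) - k + 1L
  out <- vector("list", nwin)
  for (i in seq_len(nwin)) {
    sel <- L >= i + k - 1L
    out[[i]] <- substr(reads[sel], i, i + k - 1L)
  }
  unlist(out, use.names = FALSE)
}

#' Count k-mers in a set of reads
#'
#' Counts every length-k window of every read.  Each observed k-mer string
#' (in read orientation) is tabulated, and counts are also aggregated under
#' the canonical (strand-collapsed) form, which is what the coverage cutoff
#' is applied to.  Windows containing `N` are skipped.
#'
#' @param reads Character vector of read sequences (or a data.frame with a
#'   `seq` column).
#' @param k k-mer length.
#' @return [data.table::data.table] with columns `kmer` (observed string),
#'   `count` (observed-orientation count), `canon` (canonical form), and
#'   `canon_count` (strand-collapsed count); attribute `k`.
#' @export
count_kmers <- function(reads, k) {
  if (is.data.frame(reads)) reads <- reads$seq
  stopifnot(k >= 1)
  km <- extract_kmers(reads, k)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (length(km) == 0L) {
    tab <- data.table::data.table(kmer = character(0), count = integer(0),
                                  canon = character(0), canon_count = integer(0))
    data.table::setattr(tab, "k", as.integer(k))
    return(tab)
  }
  kmer <- count <- canon <- canon_count <- NULL # data.table NSE
  tab <- data.table::data.table(kmer = km)[, list(count = .N), by = kmer]
  tab[, canon := canonical_kmer(kmer)]
  tab[, canon_count := sum(count), by = canon]
  data.table::setkey(tab, kmer)
  data.table::setattr(tab, "k", as.integer(k))
  tab[]
}

# Successor edge table of a set of k-mer vertices: u -> v iff
# suffix(u, k-1) == prefix(v, k-1) and both are vertices.
kmer_edges <- function(vertices, k) {
  if (length(vertices) == 0L) {
    return(data.table::data.table(from = character(0), to = character(0)))
  }
  from <- to <- NULL
  cand <- data.table::CJ(from = vertices, base = c("A", "C", "G", "T"))
  cand[, to := paste0(substr(from, 2L, k), cand$base)]
  cand <- cand[to %chin% vertices, list(from, to)]
  cand[]
}

#' Build a splicing-graph assembly from k-mer counts
#'
#' K-mers whose canonical count is below the cutoff `c` are discarded; the
#' de Bruijn graph over the surviving observed k-mer strings ((k-1)
#' suffix/prefix adjacency) is compacted: maximal non-branching paths become
#' unitig nodes, edges join unitigs at branch points, and weakly connected
#' components (splicing graphs) are labeled.  Node sequences are reported in
#' canonical spelling (lexicographic minimum of the spelling and its reverse
#' complement); when both strands of a path were observed, the two mirror
#' unitigs collapse into one node.
#'
#' An empty surviving k-mer set yields an empty assembly.
#'
#' @param kmer_counts Table from [count_kmers()] (same `k` as `params`).
#' @param params An [assembly_params()] setting.
#' @return Object of class `"splicing_assembly"`: list with `params`,
#'   `nodes` (data.frame: `node_id`, `sequence`, `component_id`, `n_kmers`),
#'   `edges` (data.frame: `from`, `to`), `membership` (internal k-mer to
#'   node lookup), and `counts` (`NULL` until [quantify_nodes()]).
#' @export
build_graph <- function(kmer_counts, params) {
  stopifnot(inherits(params, "assembly_params"))
  k <- params$k
  if (!is.null(attr(kmer_counts, "k")) && attr(kmer_counts, "k") != k) {
    stop("kmer_counts were built with a different k")
  }
  canon_count <- NULL
  vertices <- kmer_counts[canon_count >= params$c]$kmer
  if (length(vertices) == 0L) return(empty_assembly(params))
  paths <- unitig_paths(vertices, k)
  assembly_from_paths(paths, vertices, k, params)
}

empty_assembly <- function(params) {
  structure(list(
    params = params,
    nodes = data.frame(node_id = character(0), sequence = character(0),
                       component_id = integer(0), n_kmers = integer(0)),
    edges = data.frame(from = character(0), to = character(0)),
    membership = data.table::data.table(kmer = character(0), node_id = character(0)),
    counts = NULL
  ), class = "splicing_assembly")
}

# Decompose the vertex set into maximal non-branching paths.
# A step u -> v is unambiguous iff outdeg(u) == 1 and indeg(v) == 1; paths
# never revisit a vertex.  Vertices left over after walking from all
# non-extendable starts lie on simple cycles, which are broken at their
# lexicographically smallest vertex.  All bookkeeping is by integer index.
unitig_paths <- function(vertices, k) {
  edges <- kmer_edges(vertices, k)
  n <- length(vertices)
  from_i <- match(edges$from, vertices)
  to_i <- match(edges$to, vertices)
  outdeg <- tabulate(from_i, n)
  indeg <- tabulate(to_i, n)
  nxt <- rep(NA_integer_, n)
  sel <- outdeg[from_i] == 1L
  nxt[from_i[sel]] <- to_i[sel]
  prv <- rep(NA_integer_, n)
  sel <- indeg[to_i] == 1L
  prv[to_i[sel]] <- from_i[sel]

  p <- prv
  is_start <- is.na(p) | is.na(nxt[ifelse(is.na(p), 1L, p)]) |
    nxt[ifelse(is.na(p), 1L, p)] != seq_len(n)

  visited <- logical(n)
  walk <- function(start, stop_at_start = FALSE) {
    path <- integer(0)
    v <- start
    repeat {
      path <- c(path, v)
      visited[v] <<- TRUE
      nx <- nxt[v]
      if (is.na(nx)) break
      if (indeg[nx] != 1L) break
      if (stop_at_start && nx == start) break
      if (visited[nx]) break
      v <- nx
    }
    path
  }

  paths <- lapply(which(is_start), walk)
  leftover <- which(!visited)
  while (length(leftover) > 0L) {
    m <- leftover[order(vertices[leftover])[1]]
    paths <- c(paths, list(walk(m, stop_at_start = TRUE)))
    leftover <- which(!visited)
  }
  list(paths = lapply(paths, function(p) vertices[p]), edges = edges)
}

spell_path <- function(path, k) {
  if (length(path) == 1L) return(path[1])
  paste0(path[1], paste(substr(path[-1], k, k), collapse = ""))
}

assembly_from_paths <- function(pe, vertices, k, params) {
  paths <- pe$paths
  edges <- pe$edges
  spellings <- vapply(paths, spell_path, character(1), k = k)
  canon <- canonical_kmer(spellings) # works for any length
  node_seqs <- sort(unique(canon))
  node_ids <- paste0("n", seq_along(node_seqs))
  path_node <- node_ids[match(canon, node_seqs)]

  # vertex -> node membership (each observed k-mer lies on exactly one path)
  membership <- data.table::data.table(
    kmer = unlist(paths, use.names = FALSE),
    node_id = rep(path_node, lengths(paths))
  )
  data.table::setkey(membership, kmer)

  # node-level edges: k-mer edges not interior to a path
  pos <- data.table::data.table(
    kmer = unlist(paths, use.names = FALSE),
    path = rep(seq_along(paths), lengths(paths)),
    idx = unlist(lapply(lengths(paths), seq_len), use.names = FALSE)
  )
  data.table::setkey(pos, kmer)
  fp <- pos[edges$from]; tp <- pos[edges$to]
  interior <- fp$path == tp$path & tp$idx == fp$idx + 1L
  nedges <- unique(data.frame(from = path_node[fp$path[!interior]],
                              to = path_node[tp$path[!interior]],
                              stringsAsFactors = FALSE))
  nedges <- nedges[order(nedges$from, nedges$to), , drop = FALSE]
  rownames(nedges) <- NULL

  g <- igraph::graph_from_data_frame(
    nedges, directed = FALSE,
    vertices = data.frame(name = node_ids)
  )
  comp <- igraph::components(g)$membership[node_ids]

  nkmer <- table(factor(membership$node_id, levels = node_ids))
  nodes <- data.frame(
    node_id = node_ids,
    sequence = node_seqs,
    component_id = as.integer(comp),
    n_kmers = as.integer(nkmer),
    stringsAsFactors = FALSE
  )
  structure(list(params = params, nodes = nodes, edges = nedges,
                 membership = membership, counts = NULL),
            class = "splicing_assembly")
}

#' @export
print.splicing_assembly <- function(x, ...) {
  cat(sprintf("splicing-graph assembly %s: %d nodes, %d edges, %d components\n",
              x$params$name, nrow(x$nodes), nrow(x$edges),
              length(unique(x$nodes$component_id))))
  if (!is.null(x$counts)) {
    cat(sprintf("  quantified over %d libraries\n", ncol(x$counts)))
  }
  invisible(x)
}

#' Reference unitig enumeration by exhaustive path search
#'
#' Independent brute-force counterpart of the path compaction inside
#' [build_graph()], used for verification on tiny inputs: enumerates every
#' directed path (by recursive extension, no vertex revisited) in which each
#' internal step leaves a vertex of out-degree 1 and enters one of in-degree
#' 1, keeps the inextensible ones, de-duplicates cycle rotations (keeping
#' the rotation starting at the lexicographically smallest vertex), and
#' returns the sorted canonical spellings.  Cost is exponential in principle;
#' only use on read sets of a few hundred bases.
#'
#' @param vertices Character vector of surviving k-mer strings.
#' @param k k-mer length.
#' @return Sorted character vector of canonical node spellings.
#' @export
unitigs_bruteforce <- function(vertices, k) {
  if (length(vertices) == 0L) return(character(0))
  edges <- kmer_edges(vertices, k)
  outdeg <- table(factor(edges$from, levels = vertices))
  indeg <- table(factor(edges$to, levels = vertices))
  succ <- split(edges$to, factor(edges$from, levels = vertices))

  step_ok <- function(u, v) outdeg[[u]] == 1L && indeg[[v]] == 1L

  maximal <- list()
  extend <- function(path) {
    u <- path[length(path)]
    grew <- FALSE
    for (v in succ[[u]]) {
      if (!(v %in% path) && step_ok(u, v)) {
        grew <- TRUE
        extend(c(path, v))
      }
    }
    # front extension possible?
    front <- FALSE
    w <- path[1]
    preds <- edges$from[edges$to == w]
    for (p in preds) {
      if (!(p %in% path) && step_ok(p, w)) front <- TRUE
    }
    if (!grew && !front) maximal[[length(maximal) + 1L]] <<- path
  }
  for (v in vertices) extend(v)

  # drop paths that are sub-paths of longer maximal paths (a lone vertex of
  # a chain is found when starting mid-chain is inextensible both ways only
  # if truly maximal, but cycles produce every rotation)
  keyed <- vapply(maximal, function(p) {
    if (length(p) > 1L) {
      # rotation-invariant key for cycles: rotate to min vertex if the path
      # closes into a cycle
      u <- p[length(p)]; w <- p[1]
      closes <- any(edges$from == u & edges$to == w) &&
        all(vapply(seq_along(p), function(i) {
          j <- if (i == length(p)) 1L else i + 1L
          step_ok(p[i], p[j])
        }, logical(1)))
      if (closes) {
        r <- order(p)[1]
        p <- c(p[r:length(p)], p[seq_len(r - 1L)])
      }
    }
    paste(p, collapse = "|")
  }, character(1))
  maximal <- maximal[!duplicated(keyed)]
  keyed <- unique(keyed)
  # remove strict sub-paths
  is_sub <- vapply(seq_along(keyed), function(i) {
    any(vapply(seq_along(keyed), function(j) {
      i != j && grepl(keyed[i], keyed[j], fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  maximal <- maximal[!is_sub]
  spell <- vapply(maximal, function(p) {
    s <- spell_path(p, k)
    min(s, revcomp(s))
  }, character(1))
  sort(unique(spell))
}

#' Assign reads to assembly nodes and count per library
#'
#' Each read votes with its surviving k-mers: every length-k window of the
#' read (or of its reverse complement, whichever orientation is in the
#' graph) is looked up in the k-mer to node map, and the read is assigned to
#' the node owning the plurality of its surviving k-mers.  Ties and reads
#' with no surviving k-mer are left unassigned, so per-library node counts
#' sum to at most the library's read count.
#'
#' @param assembly A `"splicing_assembly"` from [build_graph()].
#' @param libraries Named list: `library_id` to a character vector of read
#'   sequences (or a data.frame with a `seq` column, as from
#'   [read_fastq()]).
#' @return The assembly with `counts` set: an integer matrix, nodes x
#'   libraries.
#' @export
quantify_nodes <- function(assembly, libraries) {
  stopifnot(inherits(assembly, "splicing_assembly"))
  if (is.null(names(libraries)) || any(names(libraries) == "")) {
    stop("libraries must be a named list keyed by library_id")
  }
  k <- assembly$params$k
  node_ids <- assembly$nodes$node_id
  counts <- matrix(0L, nrow = length(node_ids), ncol = length(libraries),
                   dimnames = list(node_ids, names(libraries)))
  if (nrow(assembly$membership) > 0L) {
    # lookup for both orientations; observed orientation wins on conflict
    mem <- assembly$membership
    aug <- data.table::data.table(kmer = revcomp(mem$kmer), node_id = mem$node_id)
    lookup <- rbind(mem, aug)
    lookup <- lookup[!duplicated(lookup$kmer)]
    data.table::setkey(lookup, kmer)
    for (lib in names(libraries)) {
      reads <- libraries[[lib]]
      if (is.data.frame(reads)) reads <- reads$seq
      counts[, lib] <- assign_reads(reads, lookup, k, node_ids)
    }
  }
  assembly$counts <- counts
  assembly
}

assign_reads <- function(reads, lookup, k, node_ids) {
  n_reads <- length(reads)
  if (n_reads == 0L) return(integer(length(node_ids)))
  reads <- toupper(reads)
  keep <- nchar(reads) >= k
  idx_keep <- which(keep)
  if (length(idx_keep) == 0L) return(integer(length(node_ids)))
  r <- reads[keep]
  L <- nchar(r)
  nwin <- max(L) - k + 1L
  rows <- vector("list", nwin)
  for (i in seq_len(nwin)) {
    sel <- which(L >= i + k - 1L)
    rows[[i]] <- data.table::data.table(
      read = idx_keep[sel],
      kmer = substr(r[sel], i, i + k - 1L)
    )
  }
  votes <- data.table::rbindlist(rows)
  node_id <- kmer <- read <- N <- NULL
  votes[, node_id := lookup[votes$kmer]$node_id]
  votes <- votes[!is.na(node_id)]
  if (nrow(votes) == 0L) return(integer(length(node_ids)))
  tal <- votes[, list(N = .N), by = list(read, node_id)]
  data.table::setorder(tal, read, -N)
  top <- tal[, list(node_id = node_id[1],
                    tie = .N > 1L && N[2] == N[1]), by = read]
  top <- top[!top$tie]
  as.integer(table(factor(top$node_id, levels = node_ids)))
}

#' Sweep a grid of assembly settings
#'
#' Builds and quantifies one splicing-graph assembly per (k, c) setting from
#' the pooled reads of all libraries.  Deterministic given input order.
#'
#' @param libraries Named list of read vectors/data.frames (see
#'   [quantify_nodes()]).
#' @param grid List of [assembly_params()] settings with unique names.
#' @return Named list of quantified `"splicing_assembly"` objects (names =
#'   `"k_c"` setting names).
#' @export
sweep_assemblies <- function(libraries, grid = default_assembly_grid()) {
  if (length(grid) == 0L) stop("grid must be non-empty")
  nm <- vapply(grid, function(p) p$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate (k, c) settings in grid")
  pooled <- unlist(lapply(libraries, function(x) {
    if (is.data.frame(x)) x$seq else x
  }), use.names = FALSE)
  ks <- unique(vapply(grid, function(p) p$k, integer(1)))
  counts_by_k <- lapply(ks, function(k) count_kmers(pooled, k))
  names(counts_by_k) <- as.character(ks)
  out <- lapply(grid, function(p) {
    asm <- build_graph(counts_by_k[[as.character(p$k)]], p)
    quantify_nodes(asm, libraries)
  })
  names(out) <- nm
  out
}

#' Write assembly node sequences as FASTA
#'
#' Headers follow `assembly_k_c|component|node`.
#'
#' @param assembly A `"splicing_assembly"`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_assembly_fasta <- function(assembly, path) {
  seqs <- Biostrings::DNAStringSet(assembly$nodes$sequence)
  names(seqs) <- sprintf("assembly_%s|%d|%s", assembly$params$name,
                         assembly$nodes$component_id, assembly$nodes$node_id)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
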