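#' Evidence tier of a network-analysis score
#'
#' Maps a 0-100 relationship score onto the four published evidence tiers:
#' scores above 91 are `very_strong` (p < 0.01), scores above 76 up to 91
#' are `strong` (p 0.01-0.05), scores from 40 to 76 are `medium_strong`
#' (p 0.05-0.25) and scores below 40 are `weak` (p > 0.25). The printed
#' interval notation makes 76 medium-strong and 91 strong; for real-valued
#' scores the half-open convention (76, 91] = strong, [40, 76] =
#' medium-strong is adopted. The mapping is total and mutually exclusive
#' on [0, 100].
#'
#' @param score Numeric vector of scores in `[0, 100]`.
#' @return Character vector of tiers among
#'   `c("very_strong", "strong", "medium_strong", "weak")`.
#' @examples
#' categorize_score(c(93, 85, 75, 38))
#' @export
categorize_score <- function(score) {
  score <- as.numeric(score)
  if (anyNA(score) || any(score < 0 | score > 100)) {
    stop("scores must lie in [0, 100]", call. = FALSE)
  }
  ifelse(score > 91, "very_strong",
         ifelse(score > 76, "strong",
                ifelse(score >= 40, "medium_strong", "weak")))
}

#' Load an undirected gene interactome from SIF or edge-list TSV
#'
#' Accepts Cytoscape SIF lines (`nodeA<TAB>interaction<TAB>nodeB ...`, with
#' single-token lines declaring isolated nodes and multi-target lines
#' expanded) or plain two-column TSV edge lists. Gene symbols are
#' upper-cased (matching elsewhere in the package is case-insensitive),
#' duplicate and reversed edges are collapsed, and self-loops are dropped
#' with a message; the dropped count is kept in the graph attribute
#' `n_self_loops`.
#'
#' @param path Path to a SIF or 2-column TSV file. An empty file yields an
#'   empty graph.
#' @return An undirected simple [igraph::graph].
#' @export
load_interactome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  nodes <- character(0L)
  from <- character(0L)
  to <- character(0L)
  for (k in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[k]]), "[\t ]+")[[1L]]
    if (length(tok) == 1L) {
      nodes <- c(nodes, tok)
    } else if (length(tok) == 2L) {
      from <- c(from, tok[1L]); to <- c(to, tok[2L])
    } else if (length(tok) >= 3L) {
      # SIF: source, interaction type, one or more targets
      from <- c(from, rep(tok[1L], length(tok) - 2L))
      to <- c(to, tok[-(1:2)])
    } else {
      stop("malformed interactome line ", k, " in ", path, call. = FALSE)
    }
  }
  from <- toupper(from); to <- toupper(to); nodes <- toupper(nodes)
  loop <- from == to
  if (any(loop)) {
    message("dropped ", sum(loop), " self-loop(s)")
  }
  from <- from[!loop]; to <- to[!loop]
  all_nodes <- unique(c(nodes, from, to))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE, vertices = all_nodes)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::graph_attr(g, "n_self_loops") <- sum(loop)
  g
}

#' Read motif -> effector-gene sets
#'
#' Reads effector-set definitions either from a two-column TSV
#' (`motif<TAB>gene`, one gene per row, header optional with those names)
#' or from a YAML file mapping each motif name to a list of gene symbols.
#'
#' @param path Path to a `.tsv`/`.txt` or `.yml`/`.yaml` file.
#' @return Named list: motif name -> character vector of (upper-cased)
#'   effector gene symbols. Motif names are unique and sets nonempty.
#' @export
read_effector_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    sets <- lapply(raw, function(v) toupper(as.character(v)))
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("motif", "gene") %in% names(tab))) {
      stop("effector set schema error: need columns motif, gene",
           call. = FALSE)
    }
    sets <- lapply(split(toupper(tab$gene), tab$motif), unique)
  }
  if (any(!nzchar(names(sets))) || anyDuplicated(names(sets))) {
    stop("motif names must be unique and nonempty", call. = FALSE)
  }
  if (any(vapply(sets, length, integer(1L)) == 0L)) {
    stop("every motif needs at least one effector gene", call. = FALSE)
  }
  sets
}

#' Read a gene -> score table
#'
#' @param path TSV with columns `gene` and `score` (0-100).
#' @return Data frame with `gene` (upper-cased), `score` and the derived
#'   `category` column from [categorize_score()].
#' @export
read_score_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "score") %in% names(tab))) {
    stop("score table schema error: need columns gene, score", call. = FALSE)
  }
  data.frame(gene = toupper(tab$gene), score = as.numeric(tab$score),
             category = categorize_score(tab$score),
             stringsAsFactors = FALSE)
}

# Union of all effector genes, upper-cased.
all_effectors <- function(effectors) unique(toupper(unlist(effectors)))

#' Direct interactors of each candidate within the disease neighborhood
#'
#' For every candidate gene, returns its graph neighbors restricted to the
#' union of all effector genes and the other candidates (self excluded).
#' Candidates absent from the graph get an empty set and a warning.
#'
#' @param g An interactome graph from [load_interactome()].
#' @param candidates Character vector of candidate gene symbols.
#' @param effectors Named list of effector sets from [read_effector_sets()].
#' @return Named list: candidate -> character vector of neighbor genes.
#' @export
direct_interactors <- function(g, candidates, effectors) {
  candidates <- unique(toupper(candidates))
  allowed <- union(all_effectors(effectors), candidates)
  known <- candidates %in% igraph::V(g)$name
  if (any(!known)) {
    warning("candidate(s) absent from interactome: ",
            paste(candidates[!known], collapse = ", "), call. = FALSE)
  }
  out <- lapply(candidates, function(cand) {
    if (!cand %in% igraph::V(g)$name) return(character(0L))
    nb <- igraph::neighbors(g, cand)$name
    sort(setdiff(intersect(nb, allowed), cand))
  })
  setNames(out, candidates)
}

#' Candidates with no direct tie to effectors or other candidates
#'
#' A candidate is isolated when it has no interactome edge to any effector
#' gene of any motif nor to any other candidate. Together with the
#' candidates that have a nonempty [direct_interactors()] set, the result
#' partitions the candidate set.
#'
#' @inheritParams direct_interactors
#' @return Alphabetically sorted character vector of isolated candidates.
#' @export
isolated_candidates <- function(g, candidates, effectors) {
  di <- suppressWarnings(direct_interactors(g, candidates, effectors))
  sort(names(di)[vapply(di, length, integer(1L)) == 0L])
}

#' Motifs linked to a candidate, by membership or adjacency
#'
#' Reports, for one candidate, each motif whose effector set either
#' contains the candidate itself (containment) or intersects the
#' candidate's direct graph neighborhood (adjacency). The two relations are
#' reported in separate columns; a motif can hold both.
#'
#' @param candidate A single gene symbol.
#' @param effectors Named list of effector sets.
#' @param g An interactome graph.
#' @return Data frame with columns `motif`, `containment`, `adjacency`,
#'   one row per motif with at least one relation; zero rows for an
#'   isolated non-effector candidate.
#' @export
motif_assignment <- function(candidate, effectors, g) {
  candidate <- toupper(candidate[[1L]])
  nb <- if (candidate %in% igraph::V(g)$name) {
    toupper(igraph::neighbors(g, candidate)$name)
  } else {
    character(0L)
  }
  rows <- lapply(names(effectors), function(motif) {
    set <- toupper(effectors[[motif]])
    containment <- candidate %in% set
    adjacency <- length(intersect(nb, set)) > 0L
    if (!containment && !adjacency) return(NULL)
    data.frame(motif = motif, containment = containment,
               adjacency = adjacency, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    return(data.frame(motif = character(0L), containment = logical(0L),
                      adjacency = logical(0L)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export the subnetwork around seed genes as SIF and GraphML
#'
#' Induces the subgraph on every node within `radius` hops of any seed and
#' writes it as a Cytoscape SIF file (isolated nodes as single-token lines,
#' edges as `a<TAB>pp<TAB>b`) and optionally GraphML. Node attributes
#' supplied through `node_attrs` (a data frame keyed by `gene`) are
#' attached to the graph before the GraphML export, so candidate flags,
#' control/patient ratios, two-fold flags and motif strings travel with
#' the file.
#'
#' @param g An interactome graph.
#' @param seeds Character vector of seed gene symbols.
#' @param radius Nonnegative integer hop count; 0 induces on the seeds only.
#' @param sif_path Output SIF path.
#' @param graphml_path Optional output GraphML path.
#' @param node_attrs Optional data frame with a `gene` column plus
#'   attribute columns.
#' @return Invisibly, the induced [igraph::graph].
#' @export
export_subnetwork <- function(g, seeds, radius, sif_path,
                              graphml_path = NULL, node_attrs = NULL) {
  if (radius < 0) stop("radius must be nonnegative", call. = FALSE)
  seeds <- intersect(unique(toupper(seeds)), igraph::V(g)$name)
  if (length(seeds) == 0L) {
    stop("none of the seeds are present in the graph", call. = FALSE)
  }
  hood <- igraph::ego(g, order = radius, nodes = seeds)
  keep <- unique(unlist(lapply(hood, function(v) v$name)))
  sub <- igraph::induced_subgraph(g, keep)
  if (!is.null(node_attrs)) {
    idx <- match(igraph::V(sub)$name, toupper(node_attrs$gene))
    for (col in setdiff(names(node_attrs), "gene")) {
      vals <- node_attrs[[col]][idx]
      sub <- igraph::set_vertex_attr(sub, col, value = vals)
    }
  }
  el <- igraph::as_edgelist(sub)
  connected <- unique(c(el[, 1L], el[, 2L]))
  singletons <- setdiff(igraph::V(sub)$name, connected)
  lines <- c(if (nrow(el)) paste(el[, 1L], "pp", el[, 2L], sep = "\t"),
             singletons)
  writeLines(lines, sif_path)
  if (!is.null(graphml_path)) {
    gml <- sub
    # GraphML cannot carry NA logicals; coerce attribute vectors to character
    for (attr in igraph::vertex_attr_names(gml)) {
      if (attr != "name") {
        gml <- igraph::set_vertex_attr(
          gml, attr, value = as.character(igraph::vertex_attr(gml, attr)))
      }
    }
    igraph::write_graph(gml, graphml_path, format = "graphml")
  }
  invisible(sub)
}
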