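#' Read a regulatory network from file
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`tsv`}{one arc per line, `regulator<TAB>target[<TAB>sign]`;
#'     `#`-comments and blank lines are ignored; an optional header is
#'     detected when the first data line's first two tokens equal
#'     "regulator" and "target" case-insensitively.}
#'   \item{`sif`}{`source<TAB>relation<TAB>target`; the relation is stored as
#'     the arc sign.}
#'   \item{`graphml`}{directed GraphML as written by igraph/Cytoscape; node
#'     ids taken verbatim.}
#' }
#' Duplicate arcs collapse to one; the order of first appearance in the file
#' fixes the deterministic node order used for all tie-breaking.
#'
#' @param path file path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`; `"auto"` guesses from the
#'   file extension (default `tsv`).
#' @return a [regulatory_network()].
#' @export
read_network <- function(path, format = c("auto", "tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sif = "sif", graphml = "graphml", xml = "graphml",
                     "tsv")
  }
  switch(format,
         tsv = read_network_tsv(path),
         sif = read_network_sif(path),
         graphml = read_network_graphml(path))
}

read_network_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) return(regulatory_network())
  toks <- strsplit(lines[keep], "\t", fixed = TRUE)
  first <- tolower(trimws(toks[[1]]))
  if (length(first) >= 2 && first[1] == "regulator" && first[2] == "target") {
    keep <- keep[-1]
    toks <- toks[-1]
  }
  if (!length(keep)) return(regulatory_network())
  nt <- lengths(toks)
  bad <- nt < 2
  if (any(bad))
    stop(sprintf("parse error at line %d: expected at least 2 tab-separated fields",
                 keep[which(bad)[1]]), call. = FALSE)
  from <- vapply(toks, `[[`, "", 1)
  to <- vapply(toks, `[[`, "", 2)
  sign <- ifelse(nt >= 3, vapply(toks, function(t) t[3], ""), NA_character_)
  regulatory_network(from, to, sign = sign)
}

read_network_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) return(regulatory_network())
  toks <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- lengths(toks) != 3
  if (any(bad))
    stop(sprintf("parse error at line %d: SIF needs exactly 3 tab-separated fields",
                 keep[which(bad)[1]]), call. = FALSE)
  regulatory_network(vapply(toks, `[[`, "", 1),
                     vapply(toks, `[[`, "", 3),
                     sign = vapply(toks, `[[`, "", 2))
}

read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (!igraph::is_directed(g))
    g <- igraph::as_directed(g, mode = "arbitrary")
  att <- igraph::vertex_attr_names(g)
  ids <- if ("name" %in% att) igraph::V(g)$name
         else if ("id" %in% att) igraph::V(g)$id
         else as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  sign <- if ("sign" %in% igraph::edge_attr_names(g))
    as.character(igraph::E(g)$sign) else NULL
  regulatory_network(ids[el[, 1]], ids[el[, 2]], sign = sign, nodes = ids)
}

#' Write a regulatory network to file
#'
#' @param net a [regulatory_network()].
#' @param path output path.
#' @param format `"tsv"`, `"sif"` or `"graphml"` (see [read_network()]).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    has_sign <- !all(is.na(net$arcs$sign))
    body <- if (has_sign)
      paste(net$arcs$from, net$arcs$to,
            ifelse(is.na(net$arcs$sign), "", net$arcs$sign), sep = "\t")
    else paste(net$arcs$from, net$arcs$to, sep = "\t")
    iso <- setdiff(net$nodes, unique(c(net$arcs$from, net$arcs$to)))
    if (length(iso))
      warning("TSV edge lists cannot carry isolated nodes; ",
              length(iso), " dropped", call. = FALSE)
    writeLines(body, path)
  } else if (format == "sif") {
    rel <- ifelse(is.na(net$arcs$sign), "regulates", net$arcs$sign)
    writeLines(paste(net$arcs$from, rel, net$arcs$to, sep = "\t"), path)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

# igraph view of the network (self-loops kept; solvers never use this
# directly, only the component decomposition does).
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$arcs[, c("from", "to")],
                                directed = TRUE,
                                vertices = data.frame(name = net$nodes))
}
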