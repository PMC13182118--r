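#' Number of mature-protein positions at which two variants differ
#'
#' Treats each variant as a mapping position -> residue (the reference
#' residue where no substitution is recorded) and counts the positions where
#' the two mappings disagree. Adding, removing, or changing the residue at
#' one position all give distance 1.
#'
#' @param subs_a,subs_b canonical substitution strings.
#' @return non-negative integer.
#' @export
variant_distance <- function(subs_a, subs_b) {
  a <- string_to_subs(subs_a); b <- string_to_subs(subs_b)
  pos <- union(a$mature_pos, b$mature_pos)
  if (length(pos) == 0) return(0L)
  res_a <- ifelse(pos %in% a$mature_pos,
                  a$alt_aa[match(pos, a$mature_pos)], "ref")
  res_b <- ifelse(pos %in% b$mature_pos,
                  b$alt_aa[match(pos, b$mature_pos)], "ref")
  sum(res_a != res_b)
}

#' Build a protein-variant network for one gene
#'
#' Nodes are the gene's protein variants: those detected in the dataset
#' (status `known_detected` or `novel`) and catalog entries not detected
#' (`known_undetected`). An edge connects two variants whose substitution
#' sets differ at exactly one mature-protein position; the edge label names
#' the position and the two residues (`"67: H<->P"`). Occurrence counts are
#' carried on the nodes.
#'
#' @param variants protein-variant table from [call_protein_variants()]
#'   (may be empty); all rows must belong to `gene`.
#' @param catalog a `variant_catalog` (use the updated catalog so novel
#'   names are present).
#' @param gene gene symbol.
#' @return a `variant_network`: list with `nodes`, `edges` and an igraph
#'   `graph`.
#' @export
build_network <- function(variants, catalog, gene) {
  if (nrow(variants) > 0 && any(variants$gene != gene))
    stop("variants from multiple genes; build one network per gene",
         call. = FALSE)
  cat_sub <- catalog[catalog$gene == gene, , drop = FALSE]
  nodes <- data.frame(name = cat_sub$name,
                      substitutions = cat_sub$substitutions,
                      stringsAsFactors = FALSE)
  extra <- variants[!variants$name %in% nodes$name, , drop = FALSE]
  if (nrow(extra) > 0)
    nodes <- rbind(nodes, data.frame(name = extra$name,
                                     substitutions = extra$substitutions,
                                     stringsAsFactors = FALSE))
  det <- match(nodes$name, variants$name)
  nodes$status <- ifelse(is.na(det), "known_undetected",
                         ifelse(variants$status[det] == "novel",
                                "novel", "known_detected"))
  nodes$occurrences <- ifelse(is.na(det), 0, variants$occurrences[det])

  edges <- list()
  n <- nrow(nodes)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (variant_distance(nodes$substitutions[i],
                           nodes$substitutions[j]) == 1L) {
        a <- string_to_subs(nodes$substitutions[i])
        b <- string_to_subs(nodes$substitutions[j])
        pos <- union(a$mature_pos, b$mature_pos)
        res_a <- ifelse(pos %in% a$mature_pos,
                        a$alt_aa[match(pos, a$mature_pos)], NA)
        res_b <- ifelse(pos %in% b$mature_pos,
                        b$alt_aa[match(pos, b$mature_pos)], NA)
        d <- which(is.na(res_a) | is.na(res_b) | res_a != res_b)
        d <- d[!(is.na(res_a[d]) & is.na(res_b[d]))][1]
        p <- pos[d]
        # absent substitution means the reference residue, recoverable from
        # the other variant's recorded ref_aa at that position
        aa_a <- if (p %in% a$mature_pos) a$alt_aa[a$mature_pos == p] else
          b$ref_aa[b$mature_pos == p]
        aa_b <- if (p %in% b$mature_pos) b$alt_aa[b$mature_pos == p] else
          a$ref_aa[a$mature_pos == p]
        edges[[length(edges) + 1L]] <- data.frame(
          from = nodes$name[i], to = nodes$name[j],
          label = sprintf("%d: %s<->%s", p, aa_a, aa_b),
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0),
               label = character(0), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(gene = gene, nodes = nodes, edges = edges, graph = g),
            class = "variant_network")
}

#' @export
#' @method print variant_network
print.variant_network <- function(x, ...) {
  cat(sprintf("<variant_network> %s: %d variants, %d single-substitution edges\n",
              x$gene, nrow(x$nodes), nrow(x$edges)))
  cat(sprintf("  detected known: %d, undetected known: %d, novel: %d\n",
              sum(x$nodes$status == "known_detected"),
              sum(x$nodes$status == "known_undetected"),
              sum(x$nodes$status == "novel")))
  invisible(x)
}

#' Export a variant network
#'
#' Writes the network as round-trippable GraphML, as DOT with one node class
#' per status (detected known / undetected known / novel), or as a TSV edge
#' list.
#'
#' @param net a `variant_network`.
#' @param path output file path.
#' @param format one of `"graphml"`, `"dot"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "dot", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else if (format == "dot") {
    fill <- c(known_detected = "palegreen", known_undetected = "white",
              novel = "grey80")
    lines <- c(sprintf("graph \"%s\" {", net$gene))
    for (i in seq_len(nrow(net$nodes)))
      lines <- c(lines, sprintf(
        "  \"%s\" [style=filled, fillcolor=%s, xlabel=\"%g\"];",
        net$nodes$name[i], fill[[net$nodes$status[i]]],
        net$nodes$occurrences[i]))
    for (i in seq_len(nrow(net$edges)))
      lines <- c(lines, sprintf("  \"%s\" -- \"%s\" [label=\"%s\"];",
                                net$edges$from[i], net$edges$to[i],
                                net$edges$label[i]))
    writeLines(c(lines, "}"), path)
  } else {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
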