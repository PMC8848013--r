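#' Read a genes x cells matrix from CSV
#'
#' Expects a header row of cell identifiers and gene identifiers in the
#' first column — the dialect written by [writeCountsCsv()].
#'
#' @param path CSV file path.
#' @return numeric matrix with gene rownames and cell colnames.
#' @export
readCountsCsv <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("expected gene-id column plus cell columns")
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in ", path)
    rownames(m) <- as.character(df[[1L]])
    m
}

#' Write a genes x cells matrix as CSV
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @param idColumn name of the first (gene id) column.
#' @export
writeCountsCsv <- function(m, path, idColumn = "gene_id") {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- idColumn
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write an edge list as a two-column TSV (Gene1, Gene2)
#' @param edges data.frame with \code{source} and \code{target} columns.
#' @param path output path.
#' @export
writeEdgeTsv <- function(edges, path) {
    utils::write.table(
        data.frame(Gene1 = edges$source, Gene2 = edges$target),
        path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read a reference network from a TSV edge list
#'
#' Columns \code{Gene1} and \code{Gene2} (tab-separated, with header); an
#' optional \code{Type} column marks rows as directed/undirected.
#'
#' @param path TSV path.
#' @param tfs character vector of TF identifiers.
#' @param genes optional full gene universe (defaults to the ids seen).
#' @param directed logical; interpretation of rows lacking a Type column.
#' @return A \linkS4class{GroundTruthNetwork}.
#' @export
readReferenceNetwork <- function(path, tfs, genes = NULL, directed = TRUE) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("Gene1", "Gene2") %in% colnames(df)))
        stop("expected columns Gene1 and Gene2 in ", path)
    e <- data.frame(source = df$Gene1, target = df$Gene2,
                    stringsAsFactors = FALSE)
    if (!directed) {
        e <- rbind(e, data.frame(source = e$target, target = e$source))
    }
    e <- e[e$source %in% tfs & e$source != e$target, , drop = FALSE]
    e <- e[!duplicated(edgeKey(e$source, e$target)), , drop = FALSE]
    rownames(e) <- NULL
    if (is.null(genes)) genes <- sort(unique(c(df$Gene1, df$Gene2, tfs)))
    methods::new("GroundTruthNetwork", tfs = intersect(genes, tfs),
                 genes = genes, edges = e, directed = TRUE)
}

#' Write ranked edges in the BEELINE rankedEdges dialect
#'
#' TSV with header \code{Gene1 Gene2 EdgeWeight}, sorted by rank.
#'
#' @param rel a \linkS4class{RankedEdgeList}.
#' @param path output path.
#' @export
writeRankedEdges <- function(rel, path) {
    e <- edges(rel)
    e <- e[order(e$rank, e$source, e$target), , drop = FALSE]
    utils::write.table(
        data.frame(Gene1 = e$source, Gene2 = e$target,
                   EdgeWeight = e$weight),
        path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Load an external ranked edge list (BEELINE rankedEdges dialect)
#'
#' Expects a TSV with header \code{Gene1}, \code{Gene2}, \code{EdgeWeight};
#' ranks are recomputed by competition ranking of the weights in descending
#' order. Malformed weights and duplicate edges are rejected with the
#' offending line numbers.
#'
#' @param path TSV path.
#' @param methodTag,imputationTag provenance labels for the result.
#' @return A \linkS4class{RankedEdgeList}.
#' @export
loadExternalRankedEdges <- function(path, methodTag = "external",
                                    imputationTag = NA_character_) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("Gene1", "Gene2", "EdgeWeight")
    if (!all(need %in% colnames(df)))
        stop("expected header Gene1, Gene2, EdgeWeight in ", path)
    if (nrow(df) == 0L) {
        warning("empty ranked edge file: ", path)
        return(newRankedEdgeList(character(0), character(0), numeric(0),
                                 methodTag = methodTag,
                                 imputationTag = imputationTag))
    }
    w <- suppressWarnings(as.numeric(df$EdgeWeight))
    bad <- which(!is.finite(w))
    if (length(bad))
        stop("non-numeric or NaN EdgeWeight at line(s) ",
             paste(bad + 1L, collapse = ", "))
    dup <- which(duplicated(edgeKey(df$Gene1, df$Gene2)))
    if (length(dup))
        stop("duplicate (Gene1, Gene2) rows at line(s) ",
             paste(dup + 1L, collapse = ", "))
    newRankedEdgeList(df$Gene1, df$Gene2, w, methodTag = methodTag,
                      imputationTag = imputationTag)
}

#' Write a simulated dataset and its truth to a directory
#'
#' Writes counts as genes x cells CSV, pseudotime as a two-column CSV, TFs
#' as one id per line and the ground truth as a Gene1/Gene2 TSV.
#'
#' @param data an \linkS4class{ExpressionDataset}.
#' @param net the matching \linkS4class{GroundTruthNetwork}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeSimulatedDataset <- function(data, net, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
        counts = file.path(dir, "counts.csv"),
        pseudotime = file.path(dir, "pseudotime.csv"),
        tfs = file.path(dir, "tfs.txt"),
        truth = file.path(dir, "ground_truth.tsv")
    )
    writeCountsCsv(assay(data, "counts"), paths["counts"])
    utils::write.csv(data.frame(cell_id = colnames(data),
                                pseudotime = pseudotime(data)),
                     paths["pseudotime"], row.names = FALSE, quote = FALSE)
    writeLines(names(which(tfFlags(data))), paths["tfs"])
    writeEdgeTsv(edges(net), paths["truth"])
    invisible(paths)
}
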