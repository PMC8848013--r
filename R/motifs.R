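#' Enumerate chains and feed-forward loops in a directed network
#'
#' Scans all adjacent edge pairs X -> Y, Y -> Z with distinct X, Y, Z: the
#' ordered triple is a feed-forward loop when the shortcut X -> Z is also
#' present, and a network chain when it is absent. Each ordered triple is
#' reported once; a bidirected pair can therefore generate two chains.
#'
#' @param net data.frame of directed edges (\code{source}, \code{target})
#'   or an object with an [edges()] method.
#' @return data.frame with columns X, Y, Z, kind ("chain" or "ffl").
#' @export
enumerateMotifs <- function(net) {
    e <- if (is.data.frame(net)) net else edges(net)
    if (nrow(e) == 0L)
        return(data.frame(X = character(0), Y = character(0),
                          Z = character(0), kind = character(0),
                          stringsAsFactors = FALSE))
    key <- edgeKey(e$source, e$target)
    bysrc <- split(e$target, e$source)
    X <- character(0); Y <- character(0); Z <- character(0)
    for (i in seq_len(nrow(e))) {
        x <- e$source[i]; y <- e$target[i]
        zs <- bysrc[[y]]
        if (is.null(zs)) next
        zs <- zs[zs != x & zs != y]
        if (!length(zs)) next
        X <- c(X, rep(x, length(zs))); Y <- c(Y, rep(y, length(zs)))
        Z <- c(Z, zs)
    }
    if (!length(X))
        return(data.frame(X = character(0), Y = character(0),
                          Z = character(0), kind = character(0),
                          stringsAsFactors = FALSE))
    kind <- ifelse(edgeKey(X, Z) %in% key, "ffl", "chain")
    out <- data.frame(X = X, Y = Y, Z = Z, kind = kind,
                      stringsAsFactors = FALSE)
    out <- out[order(out$X, out$Y, out$Z), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Classify predicted chain motifs against a reference network
#'
#' For every motif of the predicted network whose backbone edges X -> Y and
#' Y -> Z both exist in the reference: a predicted chain that is also a
#' chain in the reference is a TP; a predicted chain that is actually a
#' feed-forward loop in the reference is an FP; a predicted feed-forward
#' loop that is actually a chain in the reference is an FN. Predicted loops
#' agreeing with reference loops are counted separately
#' (\code{nLoopAgree}), and motifs whose backbone is missing from the
#' reference are unclassifiable; neither enters TPR or FDR.
#' TPR = TP/(TP+FN), FDR = FP/(TP+FP); a zero denominator yields NA.
#'
#' @param predEdges directed edge data.frame (or object with [edges()]) of
#'   the predicted top-k network.
#' @param refEdges directed edge data.frame of the harmonized reference.
#' @return A \linkS4class{MotifClassification}.
#' @export
classifyMotifs <- function(predEdges, refEdges) {
    pe <- if (is.data.frame(predEdges)) predEdges else edges(predEdges)
    re <- if (is.data.frame(refEdges)) refEdges else edges(refEdges)
    mot <- enumerateMotifs(pe)
    refKey <- edgeKey(re$source, re$target)
    if (nrow(mot) > 0) {
        backbone <- edgeKey(mot$X, mot$Y) %in% refKey &
                    edgeKey(mot$Y, mot$Z) %in% refKey
        refKind <- ifelse(edgeKey(mot$X, mot$Z) %in% refKey, "ffl", "chain")
        cl <- rep("unclassifiable", nrow(mot))
        cl[backbone & mot$kind == "chain" & refKind == "chain"] <- "TP"
        cl[backbone & mot$kind == "chain" & refKind == "ffl"] <- "FP"
        cl[backbone & mot$kind == "ffl" & refKind == "chain"] <- "FN"
        cl[backbone & mot$kind == "ffl" & refKind == "ffl"] <- "loop_agree"
        mot$reference_kind <- ifelse(backbone, refKind, NA_character_)
        mot$class <- cl
    } else {
        mot$reference_kind <- character(0)
        mot$class <- character(0)
    }
    nTp <- sum(mot$class == "TP")
    nFp <- sum(mot$class == "FP")
    nFn <- sum(mot$class == "FN")
    tpr <- if (nTp + nFn > 0) nTp / (nTp + nFn) else NA_real_
    fdr <- if (nTp + nFp > 0) nFp / (nTp + nFp) else NA_real_
    methods::new("MotifClassification", motifs = mot,
                 nTp = as.integer(nTp), nFp = as.integer(nFp),
                 nFn = as.integer(nFn),
                 nUnclassifiable = as.integer(sum(mot$class == "unclassifiable")),
                 nLoopAgree = as.integer(sum(mot$class == "loop_agree")),
                 tpr = tpr, fdr = fdr)
}
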