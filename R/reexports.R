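# re-exported so that users can work with ExpressionDataset assays without
# attaching SummarizedExperiment themselves

#' @importFrom SummarizedExperiment assay
#' @export
SummarizedExperiment::assay

#' @importFrom SummarizedExperiment assayNames
#' @export
SummarizedExperiment::assayNames

#' @importFrom SummarizedExperiment rowData
#' @export
SummarizedExperiment::rowData

#' @importFrom SummarizedExperiment colData
#' @export
SummarizedExperiment::colData
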