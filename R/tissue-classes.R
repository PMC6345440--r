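#' The nine colorectal tissue classes
#'
#' The fixed, alphabetical class order used for every activation vector,
#' confusion matrix, and score weight in the package: ADI (adipose tissue),
#' BACK (background), DEB (debris/necrosis), LYM (lymphocytes), MUC (mucus),
#' MUS (smooth muscle), NORM (normal colon mucosa), STR (cancer-associated
#' stroma), TUM (colorectal adenocarcinoma epithelium).
#'
#' @return Character vector of the nine class codes, in fixed order.
#' @export
#' @examples
#' tissue_classes()
tissue_classes <- function() {
  c("ADI", "BACK", "DEB", "LYM", "MUC", "MUS", "NORM", "STR", "TUM")
}

#' Display names for the nine tissue classes
#'
#' @return Named character vector mapping class code to a human-readable name.
#' @export
tissue_class_names <- function() {
  c(ADI  = "adipose tissue",
    BACK = "background",
    DEB  = "debris",
    LYM  = "lymphocytes",
    MUC  = "mucus",
    MUS  = "smooth muscle",
    NORM = "normal colon mucosa",
    STR  = "cancer-associated stroma",
    TUM  = "colorectal adenocarcinoma epithelium")
}

# Validate a class code, with an informative error listing the valid codes.
.check_class <- function(cls) {
  codes <- tissue_classes()
  if (length(cls) != 1L || !cls %in% codes) {
    stop("unknown tissue class ", deparse(cls), "; valid codes are: ",
         paste(codes, collapse = ", "), call. = FALSE)
  }
  cls
}

# Activation column names used in cohort and activation tables.
.activation_cols <- function() paste0("a_", tissue_classes())
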