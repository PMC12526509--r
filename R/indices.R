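.FAM2D <- c("ATI", "DTI", "NDTI", "RTI", "RDTI", "RATI")
.FAM3D <- c("BDSI", "DTTI", "MSI", "NDTTI")

#' Registry of the texture-index families
#'
#' Six two-dimensional families (ATI, DTI, NDTI, RTI, RDTI, RATI) over
#' position pairs and four three-dimensional families (BDSI, DTTI, MSI,
#' NDTTI) over position triples.
#'
#' @param arity `2`, `3`, or `NULL` for all.
#' @return data.frame with columns `family`, `arity`.
#' @export
indexFamilies <- function(arity = NULL) {
  out <- data.frame(family = c(.FAM2D, .FAM3D),
                    arity = c(rep(2L, length(.FAM2D)),
                              rep(3L, length(.FAM3D))),
                    stringsAsFactors = FALSE)
  if (!is.null(arity)) out <- out[out$arity == arity, , drop = FALSE]
  rownames(out) <- NULL
  out
}

indexArity <- function(family) {
  if (family %in% .FAM2D) 2L
  else if (family %in% .FAM3D) 3L
  else stop("unknown index family '", family, "'")
}

#' Evaluate a 2-D texture index
#'
#' `ATI = Ti + Tj`; `DTI = Ti - Tj`; `NDTI = (Ti - Tj)/(Ti + Tj)`;
#' `RTI = Ti/Tj`; `RDTI = 1/Ti - 1/Tj`; `RATI = 1/Ti + 1/Tj`.
#' Degenerate denominators (and non-finite inputs) yield `NA`, the
#' undefined marker, never an error — batch evaluation must not abort.
#'
#' @param family family name.
#' @param Ti,Tj position values (vectorized).
#' @return numeric vector.
#' @export
eval2d <- function(family, Ti, Tj) {
  out <- switch(family,
    ATI  = Ti + Tj,
    DTI  = Ti - Tj,
    NDTI = ifelse(Ti + Tj == 0, NA_real_, (Ti - Tj) / (Ti + Tj)),
    RTI  = ifelse(Tj == 0, NA_real_, Ti / Tj),
    RDTI = ifelse(Ti == 0 | Tj == 0, NA_real_, 1 / Ti - 1 / Tj),
    RATI = ifelse(Ti == 0 | Tj == 0, NA_real_, 1 / Ti + 1 / Tj),
    stop("unknown 2-D index family '", family, "'"))
  out[!is.finite(out)] <- NA_real_
  out
}

#' Evaluate a 3-D texture index
#'
#' `BDSI = (Ti - Tj)/(Tk - Tj)`; `DTTI = Ti - Tj - Tk`;
#' `MSI = Ti * Tj * Tk`; `NDTTI = (Ti - Tj - Tk)/(Ti + Tj + Tk)`.
#' Degenerate denominators yield `NA` (undefined marker).
#'
#' @param family family name.
#' @param Ti,Tj,Tk position values (vectorized).
#' @return numeric vector.
#' @export
eval3d <- function(family, Ti, Tj, Tk) {
  out <- switch(family,
    BDSI  = ifelse(Tk == Tj, NA_real_, (Ti - Tj) / (Tk - Tj)),
    DTTI  = Ti - Tj - Tk,
    MSI   = Ti * Tj * Tk,
    NDTTI = ifelse(Ti + Tj + Tk == 0, NA_real_,
                   (Ti - Tj - Tk) / (Ti + Tj + Tk)),
    stop("unknown 3-D index family '", family, "'"))
  out[!is.finite(out)] <- NA_real_
  out
}

#' Format / parse texture-index column labels
#'
#' Grammar: `FAMILY(LABEL,LABEL[,LABEL])` with `LABEL` a position label,
#' e.g. `"DTTI(HOM5,HOM2,SEC6)"`. `parseIndexLabel()` inverts
#' `indexLabel()` exactly.
#'
#' @param family family name.
#' @param positions character vector of 2 or 3 position labels (repetition
#'   allowed, order significant).
#' @return `indexLabel()`: the label string. `parseIndexLabel()`: list with
#'   `family`, `arity`, `positions`.
#' @export
indexLabel <- function(family, positions) {
  ar <- indexArity(family)
  if (length(positions) != ar)
    stop(family, " needs ", ar, " positions")
  paste0(family, "(", paste(positions, collapse = ","), ")")
}

#' @rdname indexLabel
#' @param label a label produced by `indexLabel()`.
#' @export
parseIndexLabel <- function(label) {
  m <- regmatches(label, regexec("^([A-Z]+)\\(([^)]+)\\)$", label))[[1]]
  if (length(m) != 3L) stop("cannot parse index label '", label, "'")
  fam <- m[2]
  pos <- strsplit(m[3], ",", fixed = TRUE)[[1]]
  if (length(pos) != indexArity(fam))
    stop("label '", label, "' has wrong arity for ", fam)
  lapply(pos, parsePosition)   # validates each position
  list(family = fam, arity = indexArity(fam), positions = pos)
}

#' Evaluate index definitions over a position matrix
#'
#' Appends one column per definition to the feature space. Rows where any
#' operand or the result is undefined carry `NA`.
#'
#' @param X plots x positions numeric matrix with position-label column
#'   names (typically from [positionMatrix()]).
#' @param labels character vector of index labels
#'   (`"FAMILY(POS,POS[,POS])"`).
#' @return plots x length(labels) matrix, columns named by label.
#' @export
batchIndices <- function(X, labels) {
  out <- matrix(NA_real_, nrow(X), length(labels),
                dimnames = list(rownames(X), labels))
  for (k in seq_along(labels)) {
    def <- parseIndexLabel(labels[k])
    missing <- setdiff(def$positions, colnames(X))
    if (length(missing))
      stop("unknown position label(s): ", paste(missing, collapse = ", "))
    v <- lapply(def$positions, function(p) X[, p])
    out[, k] <- if (def$arity == 2L) eval2d(def$family, v[[1]], v[[2]])
                else eval3d(def$family, v[[1]], v[[2]], v[[3]])
  }
  out
}
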