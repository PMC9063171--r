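# Catalogue of weight-predictive indices. Each entry maps basic descriptor
# columns (Area, Perim., Major, Minor, Circ., Feret, Skew, Kurt, MinFeret,
# AR, Round, Solidity) to an index value. `A1`/`A2` are the five-factor
# products; `Kim index` is the Area^1.32 power-law control (mm^2 basis).
catalogue_definitions <- function() {
  list(
    "Area" = function(b) b$Area,
    "Perim." = function(b) b$Perim.,
    "Major" = function(b) b$Major,
    "Minor" = function(b) b$Minor,
    "Circ." = function(b) b$Circ.,
    "Feret" = function(b) b$Feret,
    "Skew" = function(b) b$Skew,
    "Kurt" = function(b) b$Kurt,
    "MinFeret" = function(b) b$MinFeret,
    "AR" = function(b) b$AR,
    "Round" = function(b) b$Round,
    "Solidity" = function(b) b$Solidity,
    "Minor/Major" = function(b) b$Minor / b$Major,
    "MinF/Feret" = function(b) b$MinFeret / b$Feret,
    "Area/MinF" = function(b) b$Area / b$MinFeret,
    "Area/Minor" = function(b) b$Area / b$Minor,
    "MinF/Minor" = function(b) b$MinFeret / b$Minor,
    "Area/Perim." = function(b) b$Area / b$Perim.,
    "Minor/Perim." = function(b) b$Minor / b$Perim.,
    "MinF/Perim." = function(b) b$MinFeret / b$Perim.,
    "Area/Perim.^2" = function(b) b$Area / b$Perim.^2,
    "MinF*Area/Perim." = function(b) b$MinFeret * b$Area / b$Perim.,
    "Circ.*Solidity" = function(b) b$Circ. * b$Solidity,
    "Area*Circ." = function(b) b$Area * b$Circ.,
    "MinF*Circ." = function(b) b$MinFeret * b$Circ.,
    "Minor/Solidity" = function(b) b$Minor / b$Solidity,
    "MinF/Solidity" = function(b) b$MinFeret / b$Solidity,
    "Feret/Solidity" = function(b) b$Feret / b$Solidity,
    "Area*Solidity" = function(b) b$Area * b$Solidity,
    "Feret*MinF*Solidity" = function(b) b$Feret * b$MinFeret * b$Solidity,
    "Perim.*Circ." = function(b) b$Perim. * b$Circ.,
    "A1" = function(b) b$Area * b$Perim. * b$Circ. * b$Solidity * b$MinFeret,
    "A2" = function(b) b$Area * b$Perim. * b$Circ. * b$Solidity * b$Minor
  )
}

#' Names of the index catalogue
#'
#' @param selected if TRUE, only the 12 indices retained for modelling
#'   (the 10 selected indices plus the two controls `Area` and
#'   `Kim index`); otherwise the full preliminary catalogue.
#' @return character vector of index names.
#' @export
catalogue_names <- function(selected = FALSE) {
  if (selected) {
    c("Area", "Minor", "MinFeret", "Area/Perim.", "Area*Circ.",
      "Minor/Solidity", "MinF/Solidity", "Area*Solidity", "Perim.*Circ.",
      "A1", "A2", "Kim index")
  } else {
    c(names(catalogue_definitions()), "Kim index")
  }
}

#' Power-law area control index
#'
#' `Area^1.32` with the area expressed in mm^2. A power law is not
#' unit-covariant, so this index is only defined on the metric basis.
#'
#' @param area grain (or mean) projected area in mm^2, > 0.
#' @return `area^1.32`.
#' @export
kim_index <- function(area) {
  if (any(!is.finite(area) | area <= 0)) {
    stop("Kim index requires a positive area in mm^2")
  }
  area^1.32
}

#' Evaluate the predictive index catalogue
#'
#' Computes every catalogue index from a table of basic descriptors —
#' either per grain (one row per grain, e.g. from [measure_image()]) or per
#' sample (one row of mean descriptors). On the `"pixel"` basis the raw
#' pixel columns are used and `Kim index` is omitted (it requires metric
#' units); on the `"mm"` basis the `*_mm` / `Area_mm2` columns are used and
#' `Kim index` is included. Dimensionless indices are identical on both
#' bases.
#'
#' @param measurements data.frame with the descriptor columns of
#'   [measure_image()].
#' @param unit_system `"pixel"` or `"mm"`.
#' @return data.frame of index columns (plus `Label` when present), with
#'   attributes `unit_system` and `basis`.
#' @export
compute_catalogue <- function(measurements, unit_system = c("pixel", "mm")) {
  unit_system <- match.arg(unit_system)
  stopifnot(is.data.frame(measurements))
  if (unit_system == "mm") {
    needed <- c("Area_mm2", "Perim._mm", "Major_mm", "Minor_mm", "Feret_mm",
                "MinFeret_mm")
    if (!all(needed %in% names(measurements))) {
      stop("mm-basis catalogue needs metric columns (", paste(needed, collapse = ", "),
           "); supply a mm-per-pixel scale when measuring")
    }
    b <- data.frame(
      Area = measurements$Area_mm2, Perim. = measurements$"Perim._mm",
      Major = measurements$Major_mm, Minor = measurements$Minor_mm,
      Feret = measurements$Feret_mm, MinFeret = measurements$MinFeret_mm,
      Circ. = measurements$Circ., Solidity = measurements$Solidity,
      AR = measurements$AR, Round = measurements$Round,
      Skew = measurements$Skew, Kurt = measurements$Kurt,
      check.names = FALSE
    )
  } else {
    b <- measurements
  }
  defs <- catalogue_definitions()
  out <- data.frame(row.names = seq_len(nrow(measurements)))
  labels <- if ("Label" %in% names(measurements)) measurements$Label else
    seq_len(nrow(measurements))
  for (nm in names(defs)) {
    v <- defs[[nm]](b)
    bad <- !is.finite(v)
    if (any(bad)) {
      stop("index '", nm, "' is not finite for grain(s) ",
           paste(labels[bad], collapse = ", "),
           " (division by zero or missing descriptor)")
    }
    out[[nm]] <- v
  }
  if (unit_system == "mm") out[["Kim index"]] <- kim_index(b$Area)
  if ("Label" %in% names(measurements)) out <- cbind(Label = measurements$Label, out)
  attr(out, "unit_system") <- unit_system
  out
}

#' Rank indices by their correlation with mean grain weight
#'
#' Pearson correlation between each per-sample index and MGW, sorted by
#' `|R|` descending. Indices whose `|R|` strictly exceeds both controls
#' (`Area` and `Kim index`, where present) are flagged as selected.
#'
#' @param samples per-sample data.frame holding index columns and an MGW
#'   column (see [sample_table()]).
#' @param mgw_col name of the MGW column (default `"MGW"`).
#' @param controls control index names.
#' @return data.frame with columns `index`, `R`, `abs_R`, `zero_variance`,
#'   `selected`, ordered by `abs_R` descending.
#' @export
rank_indices <- function(samples, mgw_col = "MGW",
                         controls = c("Area", "Kim index")) {
  stopifnot(is.data.frame(samples), mgw_col %in% names(samples))
  if (nrow(samples) < 3) stop("need >= 3 samples with MGW to rank indices")
  idx_cols <- intersect(catalogue_names(), names(samples))
  if (length(idx_cols) == 0) stop("no catalogue index columns in `samples`")
  mgw <- samples[[mgw_col]]
  r <- vapply(idx_cols, function(nm) {
    v <- samples[[nm]]
    if (stats::sd(v) == 0) return(NA_real_)
    stats::cor(v, mgw)
  }, numeric(1))
  zero_var <- is.na(r)
  r[zero_var] <- 0
  out <- data.frame(index = idx_cols, R = unname(r), abs_R = abs(unname(r)),
                    zero_variance = unname(zero_var),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abs_R, out$index), ]
  ctrl <- out$abs_R[out$index %in% controls]
  ctrl_max <- if (length(ctrl)) max(ctrl) else -Inf
  out$selected <- out$abs_R > ctrl_max & !(out$index %in% controls)
  rownames(out) <- NULL
  out
}
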