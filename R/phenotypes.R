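## Phenotype I/O and contemporary-group adjustment.

#' Read a phenotype CSV
#'
#' Expected header: `animal_id,batch,period,CH4,DMI` (CH4 in g/day, DMI in
#' kg/day). Extra columns are carried along.
#'
#' @param path CSV file path.
#' @return data.frame with factor `batch` and `period`.
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("animal_id", "batch", "period", "CH4", "DMI")
  if (!all(need %in% colnames(df)))
    stop("phenotype CSV must have columns ", paste(need, collapse = ","))
  df$batch <- factor(df$batch)
  df$period <- factor(df$period)
  df
}

#' Derive methane yield and adjust traits for the contemporary group
#'
#' Computes methane yield `CH4y = CH4 / DMI` (g per kg dry matter intake)
#' where absent, then adjusts the requested trait for the contemporary
#' group mean in a simple linear model with the batch x period effect:
#' the adjusted value is the residual of the trait on the batch x period
#' cell mean, so residuals sum to zero within every cell.
#'
#' @param p phenotype data.frame as from [readPhenotypes()]; one row per
#'   record (an animal may appear in several periods).
#' @param trait trait column to adjust (default `"CH4y"`).
#' @return `p` with a `CH4y` column and an `adj_<trait>` residual column.
#' @export
preparePhenotypes <- function(p, trait = "CH4y") {
  if (!"CH4y" %in% colnames(p)) p$CH4y <- p$CH4 / p$DMI
  if (!trait %in% colnames(p)) stop("unknown trait: ", trait)
  cell <- interaction(p$batch, p$period, drop = TRUE)
  if (any(table(cell) == 1L))
    warning("contemporary group cell(s) with a single record: residual is 0")
  cellMean <- ave(p[[trait]], cell, FUN = mean)
  p[[paste0("adj_", trait)]] <- p[[trait]] - cellMean
  p
}

#' Average repeated records to one value per animal
#'
#' Animals measured in more than one period (batch B1 in the study design)
#' are collapsed by averaging the adjusted trait over their records.
#'
#' @param p prepared phenotype data.frame.
#' @param column column to average (e.g. `"adj_CH4y"`).
#' @return named numeric vector, one value per animal id.
#' @export
perAnimalTrait <- function(p, column) {
  agg <- tapply(p[[column]], p$animal_id, mean)
  setNames(as.numeric(agg), names(agg))
}
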