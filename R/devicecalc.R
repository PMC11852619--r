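#' Battery runtime
#'
#' Runtime in hours of a battery of the given capacity at a constant
#' discharge current: `capacity_mAh / current_mA`. The logger's 9 V
#' lithium battery is rated 700 mAh at its ~200 mA draw, i.e. 3.5 h.
#'
#' @param capacity_mAh battery capacity in milliamp-hours (>= 0).
#' @param current_mA discharge current in milliamps (> 0).
#' @return Runtime in hours.
#' @examples
#' battery_runtime(700, 200)  # 3.5
#' @export
battery_runtime <- function(capacity_mAh, current_mA) {
  if (any(current_mA <= 0)) stop("current_mA must be positive")
  if (any(capacity_mAh < 0)) stop("capacity_mAh must be >= 0")
  capacity_mAh / current_mA
}

#' Read a bill of materials
#'
#' @param path CSV with columns `name,quantity,unit_price,cost`. The
#'   packaged device BOM ships at
#'   `system.file("extdata", "biosense_bom.csv", package = "ibmkit")`.
#' @return Data frame of class `bom` with those columns.
#' @export
read_bom <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "quantity", "unit_price", "cost")
  if (!all(need %in% names(df)))
    stop("BOM must have columns ", paste(need, collapse = ", "))
  if (any(df$quantity < 0) || any(df$unit_price < 0) || any(df$cost < 0))
    stop("BOM quantities and prices must be >= 0")
  structure(df[need], class = c("bom", "data.frame"))
}

#' Total cost of a bill of materials
#'
#' Sums the printed `cost` column (rounded to cents). Rows whose cost
#' disagrees with `quantity * unit_price` by more than half a cent are
#' reported as inconsistencies — reported, never corrected, so a printed
#' total stays reproducible.
#'
#' @param items a data frame with columns `name,quantity,unit_price,cost`
#'   (e.g. from [read_bom()]).
#' @return List with `total_cost` (USD, rounded to cents) and
#'   `inconsistencies` (a data frame of the offending rows with the
#'   implied `quantity * unit_price` in `expected_cost`).
#' @export
bom_total <- function(items) {
  items <- as.data.frame(items)
  if (nrow(items) == 0L)
    return(list(total_cost = 0,
                inconsistencies = data.frame(name = character(0),
                                             quantity = numeric(0),
                                             unit_price = numeric(0),
                                             cost = numeric(0),
                                             expected_cost = numeric(0))))
  expected <- items$quantity * items$unit_price
  off <- abs(expected - items$cost) > 0.005
  inc <- items[off, c("name", "quantity", "unit_price", "cost"), drop = FALSE]
  inc$expected_cost <- round(expected[off], 2)
  rownames(inc) <- NULL
  list(total_cost = round(sum(items$cost), 2), inconsistencies = inc)
}
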