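#' Ranked movement-cost schemas
#'
#' A cost schema maps ordered cost categories (low < medium-low < medium-high
#' < high, or any custom ordered set) to strictly positive cost values. The
#' lowest category must cost at least 1, because the circuit solver cannot
#' take null resistances and fully natural cover is conventionally assigned a
#' cost of one. Category codes are the integer ranks `1..k` in ascending cost
#' order; those codes are what [category_raster()] layers carry.
#'
#' The default values span four orders of magnitude. Current-density patterns
#' are insensitive to the absolute values so long as the rank order is kept,
#' so the default only needs to preserve rank; the full scenario machinery for
#' probing absolute values lives in [scenario_table()] and
#' [scenario_correlations()].
#'
#' @param costs Named numeric vector, strictly increasing, first value >= 1.
#'   Names are the category labels in ascending cost order.
#' @param name Scenario label.
#' @return An object of class `omc_cost_schema`: `name`, `categories`
#'   (labels), `codes` (integer ranks) and `costs`.
#' @examples
#' cost_schema()
#' cost_schema(c(low = 1, mid = 50, high = 500), name = "三")
#' @export
cost_schema <- function(costs = c(low = 1, medium_low = 10,
                                  medium_high = 100, high = 1000),
                        name = "default") {
  if (is.null(names(costs)) || any(!nzchar(names(costs)))) {
    stop("`costs` must be a fully named vector", call. = FALSE)
  }
  if (length(costs) < 2L) stop("a schema needs at least 2 categories", call. = FALSE)
  if (any(diff(costs) <= 0)) {
    stop("cost values must be strictly increasing with category rank",
         call. = FALSE)
  }
  if (costs[1] < 1) stop("the lowest cost must be >= 1", call. = FALSE)
  structure(
    list(name = name, categories = names(costs),
         codes = seq_along(costs), costs = unname(as.numeric(costs))),
    class = "omc_cost_schema"
  )
}

#' @export
print.omc_cost_schema <- function(x, ...) {
  cat(sprintf("<cost schema '%s'>\n", x$name))
  print(stats::setNames(x$costs, x$categories))
  invisible(x)
}

#' Read a cost schema from YAML
#'
#' Expects `name:` and a `costs:` mapping whose entries are listed in
#' ascending rank order, e.g. `{name: C9, costs: {low: 1, medium_low: 10,
#' medium_high: 100, high: 1000}}`.
#'
#' @param path Path to a YAML file.
#' @return An `omc_cost_schema`.
#' @export
read_cost_schema <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$costs)) stop("schema YAML needs a `costs` mapping", call. = FALSE)
  cost_schema(unlist(spec$costs), name = spec$name %||% "unnamed")
}

#' Map a category code to its schema cost
#' @param schema An `omc_cost_schema`.
#' @param codes Integer category codes (rank positions).
#' @return Numeric costs.
#' @keywords internal
schema_cost <- function(schema, codes) schema$costs[codes]

#' Look up the code of a named category
#' @inheritParams schema_cost
#' @param category Category label, e.g. `"medium_low"`.
#' @keywords internal
schema_code <- function(schema, category) {
  i <- match(category, schema$categories)
  if (is.na(i)) stop("unknown category: ", category, call. = FALSE)
  i
}
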