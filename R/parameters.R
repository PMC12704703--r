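# Parameter registry: every model input with its base value, deterministic
# sensitivity-analysis range and probabilistic sampling distribution.

.icbtcea_cache <- new.env(parent = emptyenv())

.scales <- c("probability", "proportion", "rate_percent_monthly", "utility",
             "money", "count", "multiplier")
.dists <- c("beta", "gamma", "triangular", "fixed")

# Parameter pairs whose uncertainty comes from a single source study and is
# therefore sampled with a common quantile in the PSA (see run_psa()).
.correlated_pairs <- list(
  acceptance = c("accept_inperson", "accept_internet"),
  compliance = c("comply_inperson", "comply_internet")
)

default_registry_path <- function() {
  system.file("extdata", "parameters.yaml", package = "icbtcea", mustWork = TRUE)
}

read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- lapply(names(raw), function(nm) {
    x <- raw[[nm]]
    if (is.null(x$base)) stop("parameter '", nm, "' has no base value", call. = FALSE)
    data.frame(
      name = nm,
      base = as.numeric(x$base),
      low = if (is.null(x$low)) NA_real_ else as.numeric(x$low),
      high = if (is.null(x$high)) NA_real_ else as.numeric(x$high),
      dist = if (is.null(x$dist)) "fixed" else as.character(x$dist),
      scale = if (is.null(x$scale)) "count" else as.character(x$scale),
      units = if (is.null(x$units)) "" else as.character(x$units),
      label = if (is.null(x$label)) nm else as.character(x$label),
      stringsAsFactors = FALSE
    )
  })
  reg <- do.call(rbind, rows)
  bad <- setdiff(reg$dist, .dists)
  if (length(bad)) stop("unknown distribution family: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(reg$scale, .scales)
  if (length(bad)) stop("unknown scale: ", paste(bad, collapse = ", "), call. = FALSE)
  ranged <- !is.na(reg$low) & !is.na(reg$high)
  if (any(ranged != (reg$dist != "fixed")))
    stop("a parameter must have a range exactly when its distribution is not 'fixed'",
         call. = FALSE)
  reg
}

default_registry <- function() {
  if (is.null(.icbtcea_cache$registry))
    .icbtcea_cache$registry <- read_registry(default_registry_path())
  .icbtcea_cache$registry
}

new_parameters <- function(registry) {
  values <- as.list(registry$base)
  names(values) <- registry$name
  structure(values, registry = registry, class = "cea_parameters")
}

#' Load the model parameter set
#'
#' Builds the full set of model inputs: clinical event rates for the
#' decision tree, monthly Markov transition probabilities, health-state
#' utilities, unit costs, and the analysis constants (60-month horizon,
#' 1-month cycles, 3\% annual discounting, willingness-to-pay threshold of
#' US$48,119/QALY).  Defaults come from the canonical configuration shipped
#' with the package (\code{system.file("extdata", "parameters.yaml",
#' package = "icbtcea")}); event rates printed as percentages in the source
#' material are represented as fractions throughout.
#'
#' @param config \code{NULL} for the defaults, a path to a YAML/JSON file
#'   with parameter blocks (\code{base} and optionally \code{low},
#'   \code{high}, \code{dist}), or a named list/vector of base-value
#'   overrides such as \code{list(wtp = 0)}.
#' @param strict if \code{TRUE} (default), overridden base values must stay
#'   inside the parameter's sensitivity-analysis envelope
#'   \code{[low, high]}; set \code{FALSE} for extended sensitivity analyses
#'   (for example platform overhead up to US$2000).  Scale invariants
#'   (probabilities and utilities in [0, 1], non-negative costs) are always
#'   enforced.
#' @return A \code{cea_parameters} object: a named list of numeric values
#'   with the full registry (base, range, distribution family, scale, units)
#'   attached as an attribute.
#' @examples
#' p <- load_parameters()
#' p$recovery_low_cbt   # 0.639
#' p0 <- load_parameters(list(wtp = 0))
#' @seealso [make_sampler()], [sample_parameter_set()], [write_parameters()]
#' @export
load_parameters <- function(config = NULL, strict = TRUE) {
  reg <- default_registry()
  params <- new_parameters(reg)
  if (is.null(config)) return(validate_parameters(params, strict = strict))
  if (is.character(config) && length(config) == 1L) {
    overrides <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
    # full blocks may redefine ranges/distributions; bare numbers are bases
    for (nm in names(overrides)) {
      x <- overrides[[nm]]
      if (is.list(x)) {
        i <- match(nm, reg$name)
        if (is.na(i)) stop("unknown parameter: '", nm, "'", call. = FALSE)
        for (fld in intersect(names(x), c("base", "low", "high", "dist")))
          reg[i, fld] <- if (fld == "dist") as.character(x[[fld]]) else as.numeric(x[[fld]])
      }
    }
    params <- new_parameters(reg)
    flat <- overrides[!vapply(overrides, is.list, logical(1))]
    if (length(flat)) params <- set_parameters(params, flat, strict = strict)
    return(validate_parameters(params, strict = strict))
  }
  if (is.numeric(config)) config <- as.list(config)
  if (!is.list(config) || is.null(names(config)) || any(names(config) == ""))
    stop("config must be NULL, a file path, or a named list of overrides",
         call. = FALSE)
  validate_parameters(set_parameters(params, config, strict = strict), strict = strict)
}

#' @rdname load_parameters
#' @export
default_parameters <- function() load_parameters()

set_parameters <- function(params, overrides, strict = TRUE) {
  reg <- attr(params, "registry")
  unknown <- setdiff(names(overrides), reg$name)
  if (length(unknown))
    stop("unknown parameter: ", paste0("'", unknown, "'", collapse = ", "),
         call. = FALSE)
  for (nm in names(overrides)) {
    val <- as.numeric(overrides[[nm]])
    if (length(val) != 1L || !is.finite(val))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    params[[nm]] <- val
    reg$base[reg$name == nm] <- val
  }
  attr(params, "registry") <- reg
  validate_parameters(params, strict = strict)
}

validate_parameters <- function(params, strict = TRUE) {
  reg <- attr(params, "registry")
  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    v <- params[[nm]]
    if (reg$scale[i] %in% c("probability", "proportion", "utility") &&
        (v < 0 || v > 1))
      stop("parameter '", nm, "' must lie in [0, 1], got ", v, call. = FALSE)
    if (reg$scale[i] %in% c("money", "count", "multiplier") && v < 0)
      stop("parameter '", nm, "' must be non-negative, got ", v, call. = FALSE)
    if (!is.na(reg$low[i])) {
      if (!(reg$low[i] <= reg$base[i] && reg$base[i] <= reg$high[i])) {
        if (strict)
          stop("parameter '", nm, "' = ", v, " is outside its sensitivity ",
               "range [", reg$low[i], ", ", reg$high[i], "]; use strict = FALSE ",
               "for extended analyses", call. = FALSE)
      }
    }
  }
  params
}

#' Write a parameter set to a YAML configuration file
#'
#' The written file round-trips: reloading it with [load_parameters()]
#' reproduces the parameter set exactly.
#'
#' @param params a \code{cea_parameters} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(params, path) {
  reg <- attr(params, "registry")
  out <- lapply(seq_len(nrow(reg)), function(i) {
    x <- list(base = reg$base[i])
    if (!is.na(reg$low[i])) {
      x$low <- reg$low[i]
      x$high <- reg$high[i]
    }
    x$dist <- reg$dist[i]
    x$scale <- reg$scale[i]
    x$units <- reg$units[i]
    x$label <- reg$label[i]
    x
  })
  names(out) <- reg$name
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Retrieve one parameter's specification
#'
#' @param params a \code{cea_parameters} object.
#' @param name parameter name.
#' @return A list with elements \code{name}, \code{base}, \code{low},
#'   \code{high}, \code{dist}, \code{scale}, \code{units}, \code{label}.
#' @export
param_spec <- function(params, name) {
  reg <- attr(params, "registry")
  i <- match(name, reg$name)
  if (is.na(i)) stop("unknown parameter: '", name, "'", call. = FALSE)
  as.list(reg[i, ])
}

# Quantile function of the triangular(min = a, mode = m, max = b)
# distribution; handles the degenerate corners m = a and m = b.
qtriangular <- function(p, a, m, b) {
  if (b <= a) return(rep(a, length(p)))
  f <- (m - a) / (b - a)
  lower <- a + sqrt(pmax(p, 0) * (b - a) * (m - a))
  upper <- b - sqrt(pmax(1 - p, 0) * (b - a) * (b - m))
  ifelse(p < f, lower, upper)
}

#' Build a sampling distribution for one parameter
#'
#' Maps a parameter specification (base value, sensitivity range,
#' distribution family) to a concrete sampler for the probabilistic
#' sensitivity analysis.  Beta and gamma families are fitted by method of
#' moments with mean equal to the base value and standard deviation
#' \code{(high - low) / 3.92}, i.e. the printed range is read as an
#' approximate 95\% interval; the triangular family uses
#' (min = low, mode = base, max = high); \code{fixed} parameters yield a
#' degenerate sampler.
#'
#' @param spec a parameter specification as returned by [param_spec()], or
#'   any list with \code{base}, \code{low}, \code{high} and \code{dist}.
#' @return A function \code{f(n, quantiles = NULL)} returning \code{n}
#'   draws; when \code{quantiles} (values in [0, 1]) are supplied the draws
#'   are the corresponding quantiles, which is how common-quantile
#'   (correlated) sampling is implemented.  The function carries the fitted
#'   distribution as attributes (\code{family}, \code{pars}).
#' @examples
#' p <- load_parameters()
#' s <- make_sampler(param_spec(p, "rel_effect_internet"))
#' range(s(1000))   # within [0.95, 1.05]
#' @export
make_sampler <- function(spec) {
  base <- spec$base
  dist <- spec$dist
  if (identical(dist, "fixed") || is.na(spec$low)) {
    f <- function(n = 1, quantiles = NULL) {
      rep(base, if (is.null(quantiles)) n else length(quantiles))
    }
    return(structure(f, family = "fixed", pars = c(value = base)))
  }
  low <- spec$low
  high <- spec$high
  if (!(low <= base && base <= high))
    stop("invalid specification: need low <= base <= high", call. = FALSE)
  sdev <- (high - low) / 3.92
  v <- sdev^2
  if (dist == "triangular") {
    f <- function(n = 1, quantiles = NULL) {
      u <- if (is.null(quantiles)) stats::runif(n) else quantiles
      qtriangular(u, low, base, high)
    }
    return(structure(f, family = "triangular",
                     pars = c(min = low, mode = base, max = high)))
  }
  if (dist == "beta") {
    if (base <= 0 || base >= 1)
      stop("beta family needs a base value strictly inside (0, 1)", call. = FALSE)
    k <- base * (1 - base) / v - 1
    if (!is.finite(k) || k <= 0)
      stop("beta method-of-moments failed: variance too large for mean ", base,
           call. = FALSE)
    shape1 <- base * k
    shape2 <- (1 - base) * k
    f <- function(n = 1, quantiles = NULL) {
      if (is.null(quantiles)) stats::rbeta(n, shape1, shape2)
      else stats::qbeta(quantiles, shape1, shape2)
    }
    return(structure(f, family = "beta",
                     pars = c(shape1 = shape1, shape2 = shape2)))
  }
  if (dist == "gamma") {
    if (base <= 0) stop("gamma family needs a positive base value", call. = FALSE)
    shape <- base^2 / v
    rate <- base / v
    f <- function(n = 1, quantiles = NULL) {
      if (is.null(quantiles)) stats::rgamma(n, shape = shape, rate = rate)
      else stats::qgamma(quantiles, shape = shape, rate = rate)
    }
    return(structure(f, family = "gamma", pars = c(shape = shape, rate = rate)))
  }
  stop("unknown distribution family: ", dist, call. = FALSE)
}

# Precompiled sampler set: samplers are built once and reused draw after
# draw.  RNG consumption order is fixed (correlated groups first, then the
# remaining non-fixed parameters in registry order) so that a draw is fully
# determined by the seed.
make_sampler_set <- function(params, correlated_pairs = TRUE) {
  reg <- attr(params, "registry")
  groups <- if (correlated_pairs) .correlated_pairs else list()
  paired <- unlist(groups)
  singles <- setdiff(reg$name[reg$dist != "fixed"], paired)
  samplers <- lapply(c(paired, singles), function(nm)
    make_sampler(param_spec(params, nm)))
  names(samplers) <- c(paired, singles)
  list(groups = groups, singles = singles, samplers = samplers)
}

draw_values <- function(sampler_set) {
  out <- list()
  for (group in sampler_set$groups) {
    u <- stats::runif(1)
    for (nm in group) out[[nm]] <- sampler_set$samplers[[nm]](quantiles = u)
  }
  for (nm in sampler_set$singles)
    out[[nm]] <- sampler_set$samplers[[nm]](1)
  out
}

#' Draw one random parameter set for the probabilistic sensitivity analysis
#'
#' Each non-fixed parameter is drawn from the distribution produced by
#' [make_sampler()].  By default the acceptance pair and the compliance pair
#' are drawn with a common quantile within each pair (their uncertainty
#' comes from a single source study each); all other draws are independent.
#'
#' @param params the base \code{cea_parameters} set.
#' @param seed integer seed; the draw is reproducible given the seed.  When
#'   \code{NULL}, the current RNG stream is used.
#' @param correlated_pairs draw the acceptance and compliance pairs with a
#'   common quantile (default \code{TRUE}).
#' @param max_retry resample attempts before a draw violating a hard scale
#'   invariant is treated as a mis-specified distribution (an error).
#' @return A \code{cea_parameters} object with sampled values.
#' @export
sample_parameter_set <- function(params, seed = NULL, correlated_pairs = TRUE,
                                 max_retry = 100L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  reg <- attr(params, "registry")
  ss <- make_sampler_set(params, correlated_pairs)
  for (attempt in seq_len(max_retry)) {
    draw <- params
    values <- draw_values(ss)
    draw[names(values)] <- values
    reg2 <- reg
    reg2$base <- as.numeric(unlist(draw[reg$name]))
    attr(draw, "registry") <- reg2
    class(draw) <- "cea_parameters"
    ok <- tryCatch({
      validate_parameters(draw, strict = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(draw)
  }
  stop("could not draw a valid parameter set in ", max_retry,
       " attempts; check the distribution specifications", call. = FALSE)
}

#' @export
print.cea_parameters <- function(x, ...) {
  reg <- attr(x, "registry")
  cat("Model parameter set (", nrow(reg), " inputs)\n", sep = "")
  show <- data.frame(base = reg$base, low = reg$low, high = reg$high,
                     dist = reg$dist, row.names = reg$name)
  print(show, digits = 6)
  invisible(x)
}
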