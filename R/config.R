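#' Load a model configuration file
#'
#' Reads a structured model configuration in YAML (or its JSON dialect),
#' validates it against the named model's schema, fills defaults, and returns
#' the constructed model object. The `model` key selects the constructor:
#' `"game"` ([payoff_matrix()]), `"diploid"` ([diploid_locus_model()]),
#' `"twolocus"` ([two_locus_model()]), `"modifier"` ([modifier_model()]) or
#' `"group"` ([group_model()]). Unknown keys are rejected with their paths.
#'
#' @param path Path to a YAML or JSON file.
#' @return A list with `model` (the constructed object), `type`, `seed`
#'   (integer or NA) and the raw validated fields.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)  # YAML is a superset of JSON
  if (!is.list(cfg) || is.null(cfg$model)) {
    stop("config must be a mapping with a `model` key", call. = FALSE)
  }
  # YAML 1.1 reads bare `y:` / `n:` keys as booleans; map them back
  names(cfg)[names(cfg) == "TRUE"] <- "y"
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  type <- cfg$model
  seed <- if (is.null(cfg$seed)) NA_integer_ else as.integer(cfg$seed)
  schemas <- list(
    game = list(required = "payoff", optional = "tol"),
    diploid = list(required = c("payoff", "xij"), optional = character(0)),
    twolocus = list(required = c("payoff", "xg", "R"), optional = character(0)),
    modifier = list(required = c("T", "s1", "s2"),
                    optional = c("r", "mu_res", "mu_mut")),
    group = list(required = c("n", "m", "delta", "y", "xhat"),
                 optional = c("payoff", "kernel", "alpha", "beta"))
  )
  if (!type %in% names(schemas)) {
    stop(sprintf("unknown model type `%s`", type), call. = FALSE)
  }
  sch <- schemas[[type]]
  fields <- setdiff(names(cfg), c("model", "seed"))
  unknown <- setdiff(fields, c(sch$required, sch$optional))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s) under %s model: %s", type,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(sch$required, fields)
  if (length(missing)) {
    stop(sprintf("missing required key(s) for %s model: %s", type,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  pw <- function() do.call(payoff_matrix, as.list(unlist(cfg$payoff)[1:4]))
  model <- switch(type,
    game = pw(),
    diploid = diploid_locus_model(do.call(rbind, cfg$xij), pw()),
    twolocus = {
      xg <- unlist(cfg$xg)
      a <- length(cfg$xg); b <- length(cfg$xg[[1]])
      two_locus_model(array(xg, dim = c(a, b, a, b)), cfg$R, pw())
    },
    modifier = modifier_model(T = cfg$T, s1 = cfg$s1, s2 = cfg$s2,
                              r = cfg$r %||% 0,
                              mu_res = cfg$mu_res %||% 0.01,
                              mu_mut = cfg$mu_mut %||% cfg$mu_res %||% 0.01),
    group = group_model(n = cfg$n, m = cfg$m, delta = cfg$delta,
                        y = cfg$y, xhat = cfg$xhat,
                        W = if (!is.null(cfg$payoff)) pw() else NULL,
                        kernel = cfg$kernel %||% "game",
                        alpha = cfg$alpha, beta = cfg$beta))
  list(model = model, type = type, seed = seed, fields = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
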