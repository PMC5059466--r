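#' Write / read a community as plain text
#'
#' One species per row (`guild`, `mass`, `herbivore_only`), tab-separated,
#' preceded by `#`-prefixed header lines carrying the pruning threshold.
#' Links and omega are not stored: they are recomputed exactly from the
#' masses by [build_food_web()], which is the ground truth.
#'
#' @param community an `atn_community`.
#' @param file path.
#' @return `read_community` returns a linked `atn_community` when the file
#'   carries a pruning threshold, otherwise masses only.
#' @export
write_community <- function(community, file) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(community$prune_epsilon))
    writeLines(sprintf("# prune_epsilon: %.17g", community$prune_epsilon), con)
  writeLines("guild\tmass\therbivore_only", con)
  df <- data.frame(
    guild = c(rep("plant", community$S_P), rep("animal", community$S_A)),
    mass = c(community$masses_plants, community$masses_animals),
    herbivore_only = c(rep(FALSE, community$S_P), community$herbivore_only)
  )
  utils::write.table(format(df, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_community
#' @export
read_community <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  pl <- df$guild == "plant"
  comm <- new_community(df$mass[pl], df$mass[!pl],
                        herbivore_only = as.logical(df$herbivore_only[!pl]))
  eps_line <- grep("prune_epsilon", hdr, value = TRUE)
  if (length(eps_line))
    comm <- build_food_web(comm,
                           eps = as.numeric(sub(".*:", "", eps_line[1])))
  comm
}

#' Write / read a parameter set as a key-value block
#'
#' Scalar entries one per line (`key: value`); the vector-valued supply,
#' nutrient content and per-plant half-saturation matrix are flattened with
#' indexed keys. Full precision (17 significant digits) round-trips
#' exactly.
#'
#' @param p an `atn_parameters` object.
#' @param file path.
#' @export
write_parameters <- function(p, file) {
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    vapply(c("beta_cons", "beta_res_animal", "beta_res_plant", "eta_cons",
             "eta_res", "q", "c", "gamma", "R_opt", "b0", "h0", "e_P",
             "e_A", "x_A", "x_P", "metab_exp", "r0", "growth_exp", "D"),
           function(k) paste0(k, ": ", num(p[[k]])), ""),
    paste0("v: ", paste(num(p$v), collapse = " ")),
    paste0("S_supply: ", paste(num(p$S_supply), collapse = " ")),
    paste0("K: ", paste(num(as.vector(p$K)), collapse = " ")),
    paste0("K_nrow: ", nrow(p$K))
  )
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(file) {
  lines <- readLines(file)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- lapply(kv, function(x) as.numeric(strsplit(x[2], " ")[[1]]))
  names(vals) <- keys
  p <- vals[setdiff(keys, c("K", "K_nrow"))]
  p$K <- matrix(vals$K, nrow = vals$K_nrow)
  class(p) <- "atn_parameters"
  p
}

#' Write sweep records or fits as CSV
#'
#' @param x a records table from [run_sweep()] or a fits table from
#'   [fit_all_power_laws()].
#' @param file path.
#' @export
write_records <- function(x, file) {
  utils::write.csv(x, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_records
#' @export
read_records <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}
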