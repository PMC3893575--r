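#' Serialize a run record
#'
#' Writes the per-iteration records as a columnar CSV plus a JSON metadata
#' sidecar (versioned schema: run size, seed, algorithm, configuration,
#' teacher demonstrations). All analyses are recomputable from the
#' serialized record.
#'
#' @param run a `voc_run`.
#' @param prefix file prefix; `<prefix>.csv` and `<prefix>.json` are
#'   written.
#' @return Invisibly, the prefix.
#' @export
write_run <- function(run, prefix) {
  stopifnot(inherits(run, "voc_run"))
  data.table::fwrite(as.data.frame(run), paste0(prefix, ".csv"))
  meta <- list(schema = "voc_run", version = 1L, n = run$n, seed = run$seed,
               algo = run$algo, config = unclass(run$config),
               teacher = if (!is.null(run$teacher))
                 list(name = run$teacher$name,
                      demos = run$teacher$demos,
                      programs = run$teacher$programs))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_run
#' @export
read_run <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  if (!identical(meta$schema, "voc_run")) stop("not a voc_run record")
  df <- data.table::fread(paste0(prefix, ".csv"), data.table = FALSE)
  meta$config <- lapply(meta$config, function(x)
    if (is.list(x)) unlist(x) else x)
  cfg <- do.call(vd_config, meta$config[names(meta$config) %in%
                                          names(vd_config())])
  s_cols <- c("i1", "i2", "f1_1", "f1_2", "f2_1", "f2_2")
  teach <- NULL
  if (!is.null(meta$teacher) && length(meta$teacher))
    teach <- structure(list(name = meta$teacher$name,
                            demos = as.matrix(meta$teacher$demos),
                            programs = as.matrix(meta$teacher$programs)),
                       class = "vd_teacher")
  structure(list(
    n = meta$n, seed = meta$seed, algo = meta$algo, config = cfg,
    teacher = teach, m_init = NULL, s_init = NULL,
    strategy = df$strategy,
    s_g = as.matrix(setNames(df[paste0("sg_", s_cols)], s_cols)),
    m = as.matrix(df[paste0("m", 1:18)]),
    s = as.matrix(df[s_cols]),
    competence = df$competence, type = df$type, class = df$class),
    class = "voc_run")
}
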