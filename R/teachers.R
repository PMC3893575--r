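#' Build an ambient-language teacher from motor programs
#'
#' An "ambient language" is a finite set of adult speech sounds the agent
#' can choose to emulate. Each motor program is executed noise-free through
#' the dynamics and synthesizer; the resulting auditory outcomes form the
#' demonstration set. Packaged teachers produce vowel / consonant-vowel-like
#' sounds: silent first perception window (low `i1`) and full phonation in
#' the second (`i2 > 0.9`); a program whose outcome fails the `i2` check is
#' rejected, since such a sound is not a well-formed demonstration.
#'
#' @param programs matrix of 18-dim motor programs in rows (or a list of
#'   policies).
#' @param name teacher label.
#' @param config a [vd_config()] list.
#' @return A list of class `vd_teacher` with `name`, `demos` (outcomes in
#'   rows) and `programs`.
#' @seealso [teacher()] for the three packaged teachers.
#' @export
make_teacher <- function(programs, name = "teacher", config = vd_config()) {
  if (is.list(programs)) programs <- do.call(rbind, programs)
  programs <- as.matrix(programs)
  stopifnot(ncol(programs) == 18, nrow(programs) >= 1)
  ex <- execute_policies(programs, config, noise_sd = 0)
  demos <- ex$prenoise
  if (any(demos[, 2] <= config$v_threshold))
    stop("demonstration i2 must exceed ", config$v_threshold,
         " (vowel-like second phone)")
  structure(list(name = name, demos = demos, programs = ex$m),
            class = "vd_teacher")
}

#' @export
print.vd_teacher <- function(x, ...) {
  cat(sprintf("<vd_teacher> %s: %d demonstrations\n", x$name,
              nrow(x$demos)))
  print(round(x$demos, 3))
  invisible(x)
}

# Motor programs of the packaged teachers: consonant-vowel-like sounds.
# The first command holds pressure/voicing just below the phonation
# threshold and the second drives them high, so voicing switches on inside
# the first perception window (a consonant-like partial phonation whose
# level depends delicately on timing) and fills the second window (a
# vowel); teacher-specific second-command articulations give distinct
# formant patterns.
packaged_teacher_programs <- function(id) {
  prog <- function(art2) c(rep(0, 7), -0.1, -0.1, art2, 1, 1)
  arts <- switch(as.character(id),
    "1" = list(c(-1, -3, 0, 0, 0, 0, 0),    # contrast along F1 of phone 2
               c(-1, 3, 0, 0, 0, 0, 0)),
    "2" = list(c(-1, 0, 0, -3, 0, 0, 0),    # diagonal F1/F2 contrast
               c(-1, 0, 0, 3, 0, 0, 0)),
    "3" = list(c(-1.5, -1.5, 0, -2, 0, 0, 0), # localized pair
               c(-1.2, -2, 0, -1.5, 0, 0, 0)),
    stop("packaged teachers are 1, 2 and 3"))
  do.call(rbind, lapply(arts, prog))
}

#' Packaged ambient-language teachers
#'
#' Three fixed two-demonstration teachers emulating distinct speech
#' environments; teachers differ in the formant patterns of their sounds
#' while all sounds share the vowel-like profile (silent first window, full
#' phonation in the second).
#'
#' @param id teacher number (1, 2 or 3).
#' @param config a [vd_config()] list.
#' @return A `vd_teacher`.
#' @examples
#' teacher(1)$demos
#' @export
teacher <- function(id, config = vd_config()) {
  make_teacher(packaged_teacher_programs(id),
               name = paste0("teacher", id), config = config)
}
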