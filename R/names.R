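# Bundled name pools. Small frequency-weighted lists of common Brazilian
# given names and surnames; enough overlap to create genuinely ambiguous
# matching cases (shared surnames, shared given names, compound surnames).

GIVEN_MALE <- c(
  "JOSE", "JOAO", "ANTONIO", "FRANCISCO", "CARLOS", "PAULO", "PEDRO",
  "LUCAS", "LUIZ", "MARCOS", "GABRIEL", "RAFAEL", "DANIEL", "MARCELO",
  "BRUNO", "EDUARDO", "FELIPE", "RODRIGO", "MANOEL", "MATEUS", "ANDRE",
  "FERNANDO", "FABIO", "LEONARDO", "GUSTAVO", "GUILHERME", "LEANDRO",
  "TIAGO", "VINICIUS", "ALEXANDRE", "RICARDO", "SERGIO", "CLAUDIO",
  "ROBERTO", "DIEGO", "JORGE", "WELLINGTON", "ADRIANO", "ANDERSON",
  "THIAGO", "MAURICIO", "RENATO", "IGOR", "CAIO", "OTAVIO", "SAMUEL",
  "VITOR", "WAGNER", "EMERSON", "JAIR"
)

GIVEN_FEMALE <- c(
  "MARIA", "ANA", "FRANCISCA", "ANTONIA", "ADRIANA", "JULIANA", "MARCIA",
  "FERNANDA", "PATRICIA", "ALINE", "SANDRA", "CAMILA", "AMANDA", "BRUNA",
  "JESSICA", "LETICIA", "JULIA", "LUCIANA", "VANESSA", "MARIANA",
  "GABRIELA", "VERA", "VITORIA", "LARISSA", "CLAUDIA", "BEATRIZ",
  "LUZIA", "ROSANGELA", "APARECIDA", "SIMONE", "ELIANE", "RAIMUNDA",
  "SOLANGE", "TEREZA", "CRISTINA", "DANIELA", "TATIANE", "REGINA",
  "SONIA", "HELENA", "IVONE", "MARTA", "NEUSA", "ROSA", "SUELI",
  "CARLA", "DEBORA", "ELAINE", "FATIMA", "IRACEMA"
)

SURNAMES <- c(
  "SILVA", "SANTOS", "OLIVEIRA", "SOUZA", "RODRIGUES", "FERREIRA",
  "ALVES", "PEREIRA", "LIMA", "GOMES", "COSTA", "RIBEIRO", "MARTINS",
  "CARVALHO", "ALMEIDA", "LOPES", "SOARES", "FERNANDES", "VIEIRA",
  "BARBOSA", "ROCHA", "DIAS", "NASCIMENTO", "ANDRADE", "MOREIRA",
  "NUNES", "MARQUES", "MACHADO", "MENDES", "FREITAS", "CARDOSO",
  "RAMOS", "GONCALVES", "SANTANA", "TEIXEIRA", "ARAUJO", "CASTRO",
  "CORREIA", "MONTEIRO", "MOURA", "BATISTA", "CAMPOS", "DUARTE",
  "FARIAS", "MELO", "MIRANDA", "MORAES", "PINTO", "REIS", "TAVARES"
)

# draw full names and mother's names for n persons of given sexes;
# mothers share a surname with probability 0.9 so that different people can
# plausibly share mother surnames (the hard case for the decision trees)
draw_person_names <- function(sex) {
  n <- length(sex)
  given <- ifelse(sex == "male",
                  sample(GIVEN_MALE, n, replace = TRUE),
                  sample(GIVEN_FEMALE, n, replace = TRUE))
  pat <- sample(SURNAMES, n, replace = TRUE)
  mat <- sample(SURNAMES, n, replace = TRUE)
  two_surnames <- runif(n) < 0.6
  name <- ifelse(two_surnames, paste(given, mat, pat), paste(given, pat))
  mother_given <- sample(GIVEN_FEMALE, n, replace = TRUE)
  shares <- runif(n) < 0.9
  mother_sur <- ifelse(shares, mat, sample(SURNAMES, n, replace = TRUE))
  mother <- paste(mother_given, mother_sur)
  tibble(name = name, mother_name = mother)
}

#' Corrupt a name string under the configured noise model
#'
#' Applies, in order: a swap of two adjacent tokens, a drop of one interior
#' token, and independent per-character substitution (A-Z, excluding the
#' original character; spaces untouched). With all probabilities zero the
#' input is returned unchanged. Deterministic under a fixed RNG state.
#'
#' @param name character vector of non-empty uppercase names.
#' @param noise list as from [name_noise()].
#' @return corrupted character vector, same length.
#' @export
perturb_string <- function(name, noise = name_noise()) {
  n <- length(name)
  if (n == 0) return(character(0))
  stopifnot(all(nzchar(name)))
  out <- name
  # token swap / drop (rare; slow path only for hit names)
  swapf <- noise$token_swap > 0 & runif(n) < noise$token_swap
  dropf <- noise$token_drop > 0 & runif(n) < noise$token_drop
  tok_hit <- which(swapf | dropf)
  for (i in tok_hit) {
    toks <- strsplit(out[i], " ", fixed = TRUE)[[1]]
    if (swapf[i] && length(toks) >= 2) {
      j <- sample.int(length(toks) - 1L, 1L)
      toks[c(j, j + 1L)] <- toks[c(j + 1L, j)]
    }
    if (dropf[i] && length(toks) >= 3) {
      pos <- 2:(length(toks) - 1L)
      toks <- toks[-pos[sample.int(length(pos), 1L)]]
    }
    out[i] <- paste(toks, collapse = " ")
  }
  # per-character substitution on non-space positions: Bernoulli(char_sub)
  # per character, realized as a binomial count + uniform positions
  if (noise$char_sub > 0) {
    n_letters <- nchar(gsub(" ", "", out, fixed = TRUE))
    hits <- rbinom(n, n_letters, noise$char_sub)
    for (i in which(hits > 0)) {
      ch <- strsplit(out[i], "", fixed = TRUE)[[1]]
      letter_pos <- which(ch != " ")
      pos <- letter_pos[sample.int(length(letter_pos), hits[i])]
      ch[pos] <- vapply(ch[pos], function(orig) {
        sample(setdiff(LETTERS, orig), 1L)
      }, character(1), USE.NAMES = FALSE)
      out[i] <- paste(ch, collapse = "")
    }
  }
  out
}
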