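Package: erbcr
Title: ERB-Based Design of Acoustic Coordinated Reset Tones for Tonal Tinnitus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for designing and analyzing acoustic coordinated reset (CR)
    therapy tones for tonal tinnitus on the equivalent rectangular bandwidth
    (ERB) scale. Computes normal-hearing ERB values, hearing-loss-widened
    auditory filter bandwidths from an audiogram, band-edge overlap and gap
    statistics between CR tones and the tinnitus frequency, analysis of the
    legacy fixed-ratio CR tone set, and constructive solvers that place CR
    tones so that neighboring ERB-wide bands coincide, overlap, or gap by a
    prescribed relative amount. Includes audiogram reading and synthesis,
    frequency sweeps, tabular export, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
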