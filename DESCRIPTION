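Package: petrinet
Title: Place/Transition Petri Nets and Structural Invariant Analysis for
    Biological Networks
Version: 0.1.0
Authors@R:
    person("Maintainer", "Petrinet", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Model biological processes as place/transition Petri nets and
    analyze them structurally: token-game execution, incidence matrices and
    the state equation, enumeration of minimal semi-positive S- and
    T-invariants by exact Farkas-style integer elimination, exhaustive
    reachability analysis with deadlock and boundedness reporting, and
    biologically annotated analysis reports.  Nets can be supplied
    programmatically, as PNML (ISO/IEC 15909-2 place/transition subset), or
    as a plain matrix text format.  Ships a fully verified built-in model of
    dopamine and norepinephrine action in depression (the DANA net),
    together with a random-net generator for property-based testing, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
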