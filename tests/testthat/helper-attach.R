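# Ensure the installed package is attached when the suite is driven by
# testthat::test_dir() directly (test_check()/devtools::test() attach it
# themselves; this is a no-op there).
suppressPackageStartupMessages(library(cytofps))
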