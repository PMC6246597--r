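>BLG_BOVINE_SYN synthetic bovine-like beta-lactoglobulin (mature chain, constructed stand-in)
PTPEGDLEILLQKVAGTWYSLAMAASDISLLDAQSAPLRTPEVDDEALEKIDALNENKVL
VLDTDYKWENGECAQKIPAVFKLSFNPTQLEEQCHI
>BLG_CAPRINE_SYN synthetic caprine-like beta-lactoglobulin (mature chain, constructed stand-in)
PTPEGNLEILLQKVAGTWYSLAMAASDISLLDAQSAPLRTPEVDDEGLEKIDALNENKVL
VLDTDYKWENGESAQKIPAVFKLSFNPTQLEEQSHI
>BLG_OVINE_SYN synthetic ovine-like beta-lactoglobulin (mature chain, constructed stand-in)
PTPEGNLEILLQKVAGTWYSLAMAASDISLLDAQSAPLRTPEVDDEGLEKIDALNENKVL
VLDTDYKWENGESAQKIPAVFKLSFNPTQLEEQAHI
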