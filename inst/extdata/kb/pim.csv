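"ingredient","catalog","category"
"oxybutynin","priscus",
"amitriptyline","priscus",
"diazepam","priscus",
"solifenacin","forta","C"
"desfesoterodine","forta","C"
"silodosin","forta","C"
"alfuzosin","forta","C"
"pioglitazone","forta","D"
"digoxin","forta","C"
"doxazosin","forta","C"
"clonidine","forta","C"
"dimenhydrinate","forta","D"
"etoricoxib","forta","C"
"trimipramine","forta","D"
"moxonidine","forta","C"
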