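breed	group	n
Chianina	grey	23
Corsa	grey	32
Croatian Podolian	grey	24
Garfagnina	grey	23
Gascon	grey	20
Guelmoise	grey	24
Hungarian Grey	grey	24
Italian Podolian	grey	24
Marchigiana	grey	22
Maremmana	grey	24
Piedmontese	grey	20
Romagnola	grey	21
Turkish Grey	grey	23
Tyrolean Grey	grey	50
Ukrainian Grey	grey	48
Angus	reference	20
Charolais	reference	33
Holstein	reference	24
Limousin	reference	35
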