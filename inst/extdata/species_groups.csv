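species,group
Bombus muscorum,threatened
Bombus humilis,threatened
Bombus sylvarum,threatened
Bombus soroeensis,threatened
Bombus terrestris,provider
Bombus lapidarius,provider
Bombus pascuorum,provider
Bombus hypnorum,provider
Bombus pratorum,provider
Bombus hortorum,provider
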