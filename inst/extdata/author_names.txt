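smith
johnson
williams
brown
jones
garcia
miller
davis
rodriguez
martinez
hernandez
lopez
gonzalez
wilson
anderson
thomas
taylor
moore
jackson
martin
lee
perez
thompson
white
harris
sanchez
clark
ramirez
lewis
robinson
walker
young
allen
king
wright
scott
torres
nguyen
hill
flores
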