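rat
rats
mouse
mice
rodent
rodents
rabbit
rabbits
cat
cats
ferret
ferrets
guinea pig
guinea pigs
macaque
macaques
monkey
monkeys
human
humans
zebrafish
Oryctolagus cuniculus
Rattus norvegicus
Mus musculus
Macaca mulatta
Danio rerio
Wistar rat
Wistar rats
Sprague-Dawley rat
Sprague-Dawley rats
Long-Evans rat
C57BL/6 mice
wild-type mice
wild type
Genetic Absence Epilepsy Rat from Strasbourg
GAERS
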