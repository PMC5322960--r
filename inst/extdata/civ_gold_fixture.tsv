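word	orth_syll
βιολί	βι-ο-λί
κυάνιο	κυ-ά-νι-ο
ήλιος	ή-λι-ος
άγιος	ά-γι-ος
δωμάτιο	δω-μά-τι-ο
στάδιο	στά-δι-ο
σχέδιο	σχέ-δι-ο
ίδιος	ί-δι-ος
δίκιο	δί-κιο
χιόνι	χιό-νι
μπάνιο	μπά-νιο
αλογάκια	α-λο-γά-κια
ποτήρια	πο-τή-ρια
ζωγραφιά	ζω-γρα-φιά
καρδιά	καρ-διά
μιλιά	μι-λιά
βράδια	βρά-δια
σκιά	σκιά
πιάνο	πιά-νο
νιώθω	νιώ-θω
μυαλό	μυα-λό
κάποιος	κά-ποιος
ποιότητα	ποι-ό-τη-τα
ακρίβεια	α-κρί-βεια
άδεια	ά-δεια
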